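process	enzyme	ec	map_id	section	reported	expected_direction
Butyrogenesis	Acetyl-CoA acetyltransferase	2.3.1.9	map00650	correct	yes	down
Butyrogenesis	3-hydroxybutyryl-CoA dehydrogenase	1.1.1.157	map00650	correct	yes	down
Butyrogenesis	Enoyl-CoA hydratase	4.2.1.17	map00650	correct	yes	down
Butyrogenesis	Butyryl-CoA dehydrogenase	1.3.8.1	map00650	correct	yes	down
Butyrogenesis	Phosphate butyryltransferase	2.3.1.19	map00650	correct	yes	down
Butyrogenesis	Butyrate kinase	2.7.2.7	map00650	correct	yes	down
Butyrogenesis	Glutamate decarboxylase	4.1.1.15	map00650	correct	yes	down
Butyrogenesis	4-hydroxybutyryl-CoA dehydratase/vinylacetyl-CoA-Delta-isomerase	5.3.3.3;4.2.1.120	map00650	correct	yes	down
Propionogenesis	Malate dehydrogenase	1.1.1.37	map00720	correct	yes	up
Propionogenesis	Fumarate hydratase	4.2.1.2	map00720	correct	yes	up
Propionogenesis	Fumarate reductase flavoprotein	1.3.1.6	map00720	correct	yes	up
Propionogenesis	Methylmalonyl-CoA mutase	5.4.99.2	map00720	correct	yes	up
Propionogenesis	Propionyl-CoA carboxylase	6.4.1.3	map00720	correct	yes	up
Propionogenesis	Acryloyl-CoA reductase	1.3.1.95	map00640	correct	yes	up
Propionogenesis	Lactaldehyde reductase	1.1.1.77	map00640	correct	yes	up
Propionogenesis	propanediol dehydratase	4.2.1.28	map00640	correct	yes	up
Propionogenesis	Phosphate propanoyltransferase	2.3.1.222	map00640	correct	yes	up
Acetogenesis	Carbon monoxide dehydrogenase	1.2.7.4	map00720	correct	yes	down
Acetogenesis	Carbon monoxide dehydrogenase/acetyl-CoA synthase	6.2.1.1	map00650	correct	yes	down
Acetogenesis	Formate-tetrahydrofolate ligase	6.3.4.3	map00720	correct	yes	down
Acetogenesis	Methenyltetrahydrofolate cyclohydrolase	3.5.4.9	map00720	correct	yes	down
Acetogenesis	Tetrahydrofolate dehydrogenase/cyclohydrolase	1.5.1.3	map00790	correct	yes	down
Acetogenesis	Phosphate acetyltransferase	2.3.1.8	map00720	correct	yes	down
Acetogenesis	Acetate kinase	2.7.2.1	map00720	correct	yes	down
Butyrogenesis	(R)-2-hydroxyglutaryl-CoA dehydratase	4.2.1.167	None	not_reported	yes	down
Butyrogenesis	Glutaconyl-CoA decarboxylase	7.2.4.5	map00650	not_reported	no	down
Butyrogenesis	NAD-dependent 4-hydroxybutyrate dehydrogenase	1.1.1.61	map00650	not_reported	no	down
Butyrogenesis	4-hydroxybutyrate coenzyme A transferase	2.8.3.-	map00650	not_reported	no	down
Propionogenesis	Propionyl-CoA:succinate CoA transferase	2.8.3.1	map00640	not_reported	no	up
Butyrogenesis	Butyryl-CoA:acetate CoA-transferase	2.8.3.8	map00650	incorrect	yes	up
Butyrogenesis	Glutaconate CoA-transferase	2.8.3.12	map00650	incorrect	yes	up
Propionogenesis	Lactoyl-CoA dehydratase	4.2.1.54	map00640	incorrect	yes	unaltered
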