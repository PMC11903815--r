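# RFC-4180 CSV serialization.
#
# Exports must be byte-identical on re-export, independent of locale, which
# rules out write.csv (quote behaviour and string ordering vary). Fields are
# quoted iff they contain a comma, a double quote, CR or LF; embedded quotes
# are doubled; records end in "\n"; a UTF-8 header row comes first.

csvEscape <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    needs <- grepl('[",\r\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
}

# df: data.frame of atomic columns; returns a single string
formatCSV <- function(df) {
    header <- paste(csvEscape(names(df)), collapse = ",")
    if (nrow(df) == 0L)
        return(paste0(header, "\n"))
    cols <- lapply(df, function(col) {
        if (is.double(col)) csvEscape(formatNum(col)) else csvEscape(col)
    })
    body <- do.call(paste, c(cols, sep = ","))
    paste0(header, "\n", paste(body, collapse = "\n"), "\n")
}

# locale-independent numeric formatting; sentinels per the export contract
formatNum <- function(x) {
    out <- character(length(x))
    out[is.na(x)] <- "NA"   # covers the NaN (undefined) sentinel too
    out[is.infinite(x) & x > 0] <- "+inf"
    out[is.infinite(x) & x < 0] <- "-inf"
    fin <- is.finite(x)
    out[fin] <- sprintf("%.15g", x[fin])
    out
}

# byte-order (C locale) ordering so exports do not depend on the session
orderC <- function(...) order(..., method = "radix")

writeText <- function(text, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(text, con, eos = NULL, useBytes = TRUE)
    invisible(path)
}
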