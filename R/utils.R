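#' @keywords internal
"_PACKAGE"

# Percentage with one-decimal rounding, the reporting convention used in all
# summary tables.
pct1 <- function(n, total) {
  if (total == 0) return(rep(0, length(n)))
  round(100 * n / total, 1)
}

# Channel columns follow the header pattern condition:replicate (e.g. "WT:1",
# "T2:3"). Everything else is metadata.
is_channel_name <- function(x) grepl("^[^:[:space:]]+:[0-9]+$", x)

channel_columns <- function(df) names(df)[is_channel_name(names(df))]

channel_condition <- function(channels) sub(":[0-9]+$", "", channels)

# Split a semicolon-separated numeric list; "" encodes an empty list.
split_num <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

join_num <- function(x) paste(x, collapse = ";")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
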