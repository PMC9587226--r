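# Table and sequence I/O.
#
# Every file is plain text. Coordinates are 1-based inclusive throughout
# (UniProt convention), and every writer states this in a header comment so a
# written file re-read never shifts a coordinate. Missing values are written
# as the empty string, never "NA" or 0: a missing intensity means "not
# detected", which downstream is distinct from a measured zero.

FEATURE_KINDS <- c("signal_peptide", "transmembrane", "domain", "functional_region")
TOPOLOGIES <- c("type_I", "type_II", "secreted", "multipass", "other")
SCHEMA_VERSION <- "v1"

#' Read a protein FASTA file
#'
#' Headers are parsed as `>accession [topology=...]`: the first whitespace
#' token is the accession and an optional `topology=` tag (written by
#' [write_fasta()]) carries membrane topology. Unannotated proteins default to
#' topology `"other"`.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `accession`, `sequence` (uppercased) and
#'   `topology`, one row per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  empty <- data.frame(accession = character(0), sequence = character(0),
                      topology = character(0), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stopf("malformed FASTA '%s': %s", path,
                                             conditionMessage(e)))
  if (length(seqs) == 0) return(empty)
  headers <- names(seqs)
  acc <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(acc))
    stopf("duplicate accession(s) in FASTA: %s",
          paste(unique(acc[duplicated(acc)]), collapse = ", "))
  topo <- rep("other", length(acc))
  m <- regmatches(headers, regexpr("topology=[A-Za-z_]+", headers))
  has <- grepl("topology=", headers)
  topo[has] <- sub("topology=", "", m)
  bad <- !topo %in% TOPOLOGIES
  if (any(bad)) stopf("unknown topology '%s' in FASTA header", topo[bad][1])
  out <- data.frame(accession = unname(acc),
                    sequence = unname(toupper(as.character(seqs))),
                    topology = topo, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a protein FASTA file
#'
#' Inverse of [read_fasta()]: topology is embedded in the header as a
#' `topology=` tag so a round trip preserves it.
#'
#' @param proteome Data frame with `accession`, `sequence`, `topology`.
#' @param path Output path.
#' @export
write_fasta <- function(proteome, path) {
  x <- Biostrings::AAStringSet(proteome$sequence)
  names(x) <- paste0(proteome$accession, " topology=", proteome$topology)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Shared TSV writer: schema comment line, coordinate convention line, then a
# tab table with missing values as "".
write_tsv <- function(df, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# oglyco %s %s", schema, SCHEMA_VERSION),
               "# coordinates: 1-based inclusive"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          na.strings = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  df
}

#' Read a protein feature annotation table
#'
#' Tab-separated with columns `accession`, `kind`, `start`, `end`, `label`.
#' Kinds are restricted to signal_peptide, transmembrane, domain and
#' functional_region; domain features must carry a non-empty label.
#' Coordinates are validated locally (integer, `start <= end`); validation
#' against protein lengths happens where proteins are available, in the
#' region mapper.
#'
#' @param path Path to the feature TSV.
#' @return Data frame of features; `label` is `""` where absent.
#' @export
read_features <- function(path) {
  df <- read_tsv(path)
  need <- c("accession", "kind", "start", "end", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("feature table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df <- df[need]
  df$label[is.na(df$label)] <- ""
  for (i in seq_len(nrow(df))) {
    if (!df$kind[i] %in% FEATURE_KINDS)
      stopf("row %d: unknown feature kind '%s'", i, df$kind[i])
    s <- suppressWarnings(as.integer(df$start[i]))
    e <- suppressWarnings(as.integer(df$end[i]))
    if (is.na(s) || is.na(e))
      stopf("row %d: non-integer coordinates", i)
    if (s < 1 || s > e)
      stopf("row %d: invalid interval %s..%s (need 1 <= start <= end)",
            i, df$start[i], df$end[i])
    if (df$kind[i] == "domain" && !nzchar(df$label[i]))
      stopf("row %d: domain feature requires a non-empty label", i)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write a feature annotation table
#' @param features Feature data frame.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  write_tsv(features, path, "features")
}

validate_psms <- function(df) {
  chans <- channel_columns(df)
  if (length(chans) == 0)
    stopf("PSM table has no channel intensity columns (pattern condition:replicate)")
  for (ch in chans) {
    v <- df[[ch]]
    if (any(!is.na(v) & v < 0)) {
      i <- which(!is.na(v) & v < 0)[1]
      stopf("row %d: negative intensity in channel %s", i, ch)
    }
  }
  for (i in seq_len(nrow(df))) {
    pos <- split_num(df$site_positions[i])
    prob <- split_num(df$site_probabilities[i])
    if (length(pos) != length(prob))
      stopf("row %d: site_positions and site_probabilities differ in length", i)
    if (!df$frag_type[i] %in% c("ETD", "HCD"))
      stopf("row %d: unknown frag_type '%s'", i, df$frag_type[i])
    plen <- df$pep_end[i] - df$pep_start[i] + 1L
    if (plen != nchar(df$peptide[i]))
      stopf("row %d: peptide coordinates span %d residues but sequence has %d",
            i, plen, nchar(df$peptide[i]))
    if (length(pos) && any(pos < 1 | pos > nchar(df$peptide[i])))
      stopf("row %d: site position outside peptide", i)
  }
  df
}

#' Read a glycopeptide-spectrum-match (PSM) table
#'
#' Emulates a search-engine PSM export: one row per spectral match with
#' peptide sequence, protein coordinates, glycan composition (HexNAc/Hex
#' counts), semicolon-separated site positions (peptide-relative, 1-based)
#' with their localization probabilities (percent), fragmentation type
#' (ETD/HCD), a quality score, and one reporter-intensity column per TMT
#' channel named `condition:replicate`. Empty intensity cells are read as
#' missing (`NA`), meaning "not detected".
#'
#' @param path Path to the PSM TSV.
#' @return Data frame of PSMs with attribute `"channels"` listing the
#'   intensity column names.
#' @export
read_psm_table <- function(path) {
  df <- read_tsv(path)
  need <- c("psm_id", "precursor_id", "peptide", "accession", "pep_start",
            "pep_end", "hexnac_count", "hex_count", "site_positions",
            "site_probabilities", "frag_type", "psm_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("PSM table missing column(s): %s",
                          paste(miss, collapse = ", "))
  for (col in c("site_positions", "site_probabilities")) {
    df[[col]][is.na(df[[col]])] <- ""
    df[[col]] <- as.character(df[[col]])
  }
  df <- validate_psms(df)
  attr(df, "channels") <- channel_columns(df)
  df
}

#' Write a PSM table
#' @param psms PSM data frame.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  write_tsv(psms, path, "psm_table")
}

#' Read an MS1 glycoform peak-area table
#'
#' Skyline-export-like: one row per (peptide region, glycoform, charge,
#' replicate) with MS1 peak area, signed mass error (ppm), isotopic dot
#' product, and retention-time offset from the region median (minutes).
#' Glycoform 0 is the non-glycosylated peptide.
#'
#' @param path Path to the peak TSV.
#' @return Data frame of peaks.
#' @export
read_peak_table <- function(path) {
  df <- read_tsv(path)
  need <- c("peak_id", "accession", "region_id", "pep_start", "pep_end",
            "peptide", "glycoform", "charge", "area", "mass_error_ppm",
            "idotp", "rt_delta_min", "replicate", "id_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("peak table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(!is.na(df$area) & df$area < 0)) stopf("negative peak area")
  if (any(!is.na(df$idotp) & (df$idotp < 0 | df$idotp > 1)))
    stopf("idotp outside [0,1]")
  df
}

#' Write an MS1 peak table
#' @param peaks Peak data frame.
#' @param path Output path.
#' @export
write_peak_table <- function(peaks, path) {
  write_tsv(peaks, path, "peak_table")
}

#' Write / read a glycosite catalog table
#'
#' @param catalog Catalog data frame from [build_catalog()].
#' @param path File path.
#' @return `read_site_catalog()` returns the catalog data frame.
#' @export
write_site_catalog <- function(catalog, path) {
  write_tsv(as.data.frame(catalog), path, "site_catalog")
}

#' @rdname write_site_catalog
#' @export
read_site_catalog <- function(path) {
  df <- read_tsv(path)
  class(df) <- c("glyco_catalog", "data.frame")
  df
}

#' Write / read a patch table (BED-like, 1-based inclusive)
#' @param patches Patch data frame from [find_patches()].
#' @param path File path.
#' @export
write_patches <- function(patches, path) {
  write_tsv(as.data.frame(patches), path, "patches")
}

#' @rdname write_patches
#' @export
read_patches <- function(path) read_tsv(path)

#' Write / read a regulation-call table
#' @param calls Long-format calls from [differential_panel()] or [test_sites()].
#' @param path File path.
#' @export
write_regulation <- function(calls, path) {
  write_tsv(as.data.frame(calls), path, "regulation")
}

#' @rdname write_regulation
#' @export
read_regulation <- function(path) read_tsv(path)

#' Write / read an occupancy table
#' @param records Occupancy data frame from [occupancy_table()].
#' @param path File path.
#' @export
write_occupancy <- function(records, path) {
  write_tsv(as.data.frame(records), path, "occupancy")
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path) read_tsv(path)

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers are returned numeric.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stopf("malformed config line: '%s'", ln)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
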