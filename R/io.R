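# Tab-separated readers/writers for the study's table formats. Writers and
# readers are exact inverses on integer count tables (bit-identical
# round-trips); floating-point tables are written at full double precision.

#' Write / read an OTU table in legacy tab-separated format
#'
#' The on-disk layout follows the classic QIIME convention: taxa as rows,
#' a leading `#OTU ID` column, one column per sample, and a trailing
#' `taxonomy` column with the semicolon-separated lineage.
#'
#' @param table an [otu_table()].
#' @param path file path.
#' @return `read_otu_table()` returns an `otu_table`; `write_otu_table()`
#'   returns `path` invisibly.
#' @export
write_otu_table <- function(table, path) {
  m <- t(table$counts)  # taxa x samples on disk
  lines <- c(
    paste(c("#OTU ID", rownames(table$counts), "taxonomy"), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i)
      paste(c(rownames(m)[i], format(m[i, ], scientific = FALSE, trim = TRUE),
              table$taxonomy[i]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "#OTU ID" || header[length(header)] != "taxonomy")
    stop("expected '#OTU ID' leading and 'taxonomy' trailing columns")
  samples <- header[-c(1, length(header))]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  otu_ids <- vapply(body, `[`, "", 1L)
  taxonomy <- vapply(body, function(f) f[length(f)], "")
  counts <- t(vapply(body, function(f)
    as.numeric(f[-c(1, length(f))]), numeric(length(samples))))
  if (length(samples) == 1L) counts <- matrix(counts, ncol = 1L)
  dimnames(counts) <- list(otu_ids, samples)
  otu_table(t(counts), taxonomy)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic study to a directory
#'
#' Writes `algal_otus.tsv` and `bacterial_otus.tsv` (legacy OTU format),
#' `metadata.tsv` (per-sample location and geochemistry), `sites.tsv`
#' (radiometer readings and cell data), and `generation_log.json`
#' (configuration, seed and package version).
#'
#' @param study a `snow_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(study$algal, file.path(dir, "algal_otus.tsv"))
  write_otu_table(study$bacterial, file.path(dir, "bacterial_otus.tsv"))
  meta_cols <- c("sample_id", "location", names(study$config$geochem_vars))
  write_tsv(study$sites[, meta_cols], file.path(dir, "metadata.tsv"))
  site_cols <- setdiff(names(study$sites), names(study$config$geochem_vars))
  write_tsv(study$sites[, site_cols], file.path(dir, "sites.tsv"))
  log <- list(package = "redsnow",
              version = as.character(utils::packageVersion("redsnow")),
              seed = study$seed, config = unclass(study$config))
  jsonlite::write_json(log, file.path(dir, "generation_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic study back from a directory
#'
#' Inverse of [write_study()]; validates that the sample ids of the OTU
#' tables, metadata and site table agree.
#'
#' @param dir directory written by [write_study()].
#' @return A `snow_study` list (`algal`, `bacterial`, `sites`, `config`,
#'   `seed`).
#' @export
read_study <- function(dir) {
  needed <- c("algal_otus.tsv", "bacterial_otus.tsv", "metadata.tsv",
              "sites.tsv", "generation_log.json")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing) > 0L)
    stop("study directory is missing: ", paste(missing, collapse = ", "))
  algal <- read_otu_table(file.path(dir, "algal_otus.tsv"))
  bacterial <- read_otu_table(file.path(dir, "bacterial_otus.tsv"))
  meta <- utils::read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE)
  sites <- utils::read.delim(file.path(dir, "sites.tsv"), stringsAsFactors = FALSE)
  log <- jsonlite::read_json(file.path(dir, "generation_log.json"),
                             simplifyVector = TRUE)
  sites <- merge(sites, meta[, setdiff(names(meta), "location")],
                 by = "sample_id", sort = FALSE)
  ids <- sites$sample_id
  if (!identical(rownames(algal$counts), ids) ||
      !identical(rownames(bacterial$counts), ids))
    stop("sample ids differ between OTU tables and site metadata")
  structure(list(algal = algal, bacterial = bacterial, sites = sites,
                 config = log$config, seed = log$seed),
            class = "snow_study")
}
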