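# Plain-text interchange formats: pulldown tables and null gene sets as
# TSV, disease models and simulation truth as JSON.

#' Read / write pulldown tables
#'
#' TSV with header `drug cell_type replicate competed protein is_kinase
#' spectral_count seq_coverage_pct`.
#'
#' @param path file path.
#' @rdname pulldown_io
#' @export
read_pulldowns <- function(path) {
  if (!file.exists(path)) stopf("pulldown table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$competed <- as.logical(df$competed)
  df$is_kinase <- as.logical(df$is_kinase)
  check_pulldown_records(df)
}

#' @param records pulldown data frame.
#' @rdname pulldown_io
#' @export
write_pulldowns <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write disease models as JSON
#'
#' Average-patient form: `{"genes": {"IKZF1": 0.84, ...}, "driver": "..."}`.
#' Copy-number form: `{"copy_numbers": {...}, "deleted_below": -0.5,
#' "driver": "..."}`.
#'
#' @param path file path.
#' @rdname disease_io
#' @export
read_disease_model <- function(path) {
  if (!file.exists(path)) stopf("disease model not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$genes)) obj$genes <- unlist(obj$genes)
  if (!is.null(obj$copy_numbers)) obj$copy_numbers <- unlist(obj$copy_numbers)
  structure(obj, class = "disease_spec")
}

#' @param model disease model list.
#' @rdname disease_io
#' @export
write_disease_model <- function(model, path) {
  obj <- unclass(model)
  # named numerics must serialize as JSON objects, not bare arrays
  for (f in c("genes", "copy_numbers"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.list(obj[[f]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write null disease gene sets
#'
#' One gene set per line, accessions tab-separated.
#'
#' @param path file path.
#' @rdname nullset_io
#' @export
read_null_sets <- function(path) {
  if (!file.exists(path)) stopf("null gene-set file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
}

#' @param sets list of character vectors.
#' @rdname nullset_io
#' @export
write_null_sets <- function(sets, path) {
  writeLines(vapply(sets, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' Write a target profile as TSV
#'
#' Columns `protein is_kinase A_score verdict cell_type_of_max`.
#'
#' @param profile a `target_profile` (merged).
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  p <- profile$provenance
  out <- data.frame(protein = p$protein, is_kinase = p$is_kinase,
                    A_score = p$A, verdict = p$verdict,
                    cell_type_of_max = p$cell_type)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_truth_json <- function(truth, path) {
  obj <- list(
    planted_targets = lapply(truth$planted_targets, as.list),
    indirect_binders = truth$indirect_binders,
    background_binders = truth$background_binders,
    kinase_flags = as.list(truth$kinase_flags),
    effective_drug = truth$effective_drug
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
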