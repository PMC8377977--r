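#' Readers and writers for the pipeline's plain-text formats
#'
#' Expression matrices travel as TSV (first column the gene ID, remaining
#' columns sample IDs), dose-response curves and result tables as CSV,
#' gene sets as GMT, and models / ground truth / reports as JSON. Parsing
#' is strict: ragged rows, duplicate identifiers and malformed records are
#' errors naming the offenders.
#'
#' @name io
NULL

#' Read a genes x samples expression matrix from TSV
#'
#' @param path TSV file; first column gene IDs, remaining columns one per
#'   sample.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, fill = FALSE)
  if (ncol(dt) < 2L) stop("expression TSV needs a gene column plus samples")
  ids <- as.character(dt[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicated gene ID(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @param expr Matrix to write.
#' @param gene_column Header for the gene-ID column.
#' @export
write_expression <- function(expr, path, gene_column = "gene_id") {
  # %.17g guarantees the written decimal reads back to the same double
  chr <- matrix(sprintf("%.17g", expr), nrow = nrow(expr),
                dimnames = dimnames(expr))
  df <- data.table::data.table(gene_id = rownames(expr))
  data.table::setnames(df, "gene_id", gene_column)
  out <- cbind(df, data.table::as.data.table(chr))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read dose-response curves from CSV
#'
#' Expected columns: `sample_id`, `dose_gy`, `surviving_fraction` (an
#' optional `clipped` column is carried through).
#'
#' @param path CSV file.
#' @return Long-format data.frame.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE, fill = FALSE)
  need <- c("sample_id", "dose_gy", "surviving_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("curve CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df
}

#' @rdname read_curves
#' @param curves Long-format curve data.frame to write.
#' @export
write_curves <- function(curves, path) {
  data.table::fwrite(curves, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`; lines with
#' fewer than three fields (i.e. no members) and duplicate set names are
#' errors reporting the line number.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("GMT line(s) without members at line ",
         paste(bad, collapse = ", "), " in ", path)
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup) > 0L) {
    stop("duplicated gene-set name(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  sets <- lapply(fields, function(f) f[-c(1L, 2L)])
  names(sets) <- nms
  structure(
    list(sets = sets,
         descriptions = stats::setNames(
           vapply(fields, `[[`, character(1), 2L), nms)),
    class = "gene_set_collection"
  )
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` to write.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a radiosensitivity profile table (CSV)
#'
#' Columns: `sample_id`, `sf2`, `auc`, `alpha`, `beta`, `rss`.
#'
#' @param profile A `radio_response_profile` data.frame.
#' @param path CSV path.
#' @export
write_profiles <- function(profile, path) {
  data.table::fwrite(profile, path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("sample_id", "sf2") %in% names(df))) {
    stop("profile CSV must contain sample_id and sf2 columns")
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicated sample ID(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  class(df) <- c("radio_response_profile", "data.frame")
  df
}

#' Serialize a fitted model to JSON and back
#'
#' The JSON carries the family name, selected genes, coefficients,
#' intercept, hyperparameters and (for the ensemble) the per-gene
#' univariate models, so a written model predicts identically after
#' [read_model()].
#'
#' @param model A fitted `radbench_model`.
#' @param path JSON path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "radbench_model"))
  payload <- list(
    name = model$name,
    selected_genes = model$selected_genes,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    hyperparameters = model$hyperparameters,
    package_version = as.character(utils::packageVersion("radbench"))
  )
  if (!is.null(model$univariate)) payload$univariate <- model$univariate
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- unlist(p$coefficients)
  if (is.null(co)) co <- stats::setNames(numeric(0), character(0))
  m <- new_model(p$name, as.character(p$selected_genes), co,
                 p$intercept, hyper = p$hyperparameters,
                 extra = if (!is.null(p$univariate)) {
                   list(univariate = as.data.frame(p$univariate))
                 } else list(),
                 fitted_values = NULL)
  m
}

#' Write a cohort's ground truth as a JSON sidecar
#'
#' @param truth The `truth` element of a `radbench_cohort`.
#' @param path JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(signal_gene_ids = truth$signal_gene_ids,
         effects = as.list(truth$effects),
         alpha = as.list(truth$alpha),
         beta = as.list(truth$beta),
         true_sf2 = as.list(truth$true_sf2),
         tissue = as.list(truth$tissue)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
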