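# Stoichiometric model representation, file I/O, partitioning and rank checks.

#' Construct a stoichiometric model
#'
#' A metabolic model is an m x n stoichiometric matrix `S` with metabolite
#' identifiers as row names and reaction identifiers as column names.  The
#' sign convention is production-positive: `S[i, j] = +1` means reaction `j`
#' produces one unit of metabolite `i`.
#'
#' @param S numeric matrix with unique, non-empty row and column names.
#' @param exchange character vector of reaction ids whose fluxes are measured
#'   exchange fluxes (may be empty; the measurement table given to
#'   [partition_model()] also designates exchanges).
#' @param allow_orphans skip the orphan-species check (used by model-reduction
#'   utilities when the caller explicitly allows stranded metabolites).
#' @return An object of class `flux_model`: a list with elements `S`,
#'   `metabolite_ids`, `reaction_ids` and `exchange_ids`.
#' @examples
#' S <- matrix(c(1, -1, 0, 1), 2, 2,
#'             dimnames = list(c("A", "B"), c("R1", "R2")))
#' flux_model(S)
#' @export
flux_model <- function(S, exchange = character(), allow_orphans = FALSE) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (anyNA(S)) stop("stoichiometric matrix contains non-numeric or missing cells")
  rn <- rownames(S)
  cn <- colnames(S)
  if (is.null(rn) || is.null(cn)) stop("S must carry metabolite row names and reaction column names")
  if (anyDuplicated(rn)) stop("duplicate metabolite ids: ", paste(unique(rn[duplicated(rn)]), collapse = ", "))
  if (anyDuplicated(cn)) stop("duplicate reaction ids: ", paste(unique(cn[duplicated(cn)]), collapse = ", "))
  zero_rows <- rowSums(S != 0) == 0
  if (any(zero_rows) && !allow_orphans) {
    stop("orphan species ", paste(rn[zero_rows], collapse = ", "),
         ": every metabolite must participate in at least one reaction")
  }
  if (!all(exchange %in% cn)) {
    stop("unknown exchange reaction id(s): ",
         paste(setdiff(exchange, cn), collapse = ", "))
  }
  structure(list(S = S,
                 metabolite_ids = rn,
                 reaction_ids = cn,
                 exchange_ids = as.character(exchange)),
            class = "flux_model")
}

#' @export
print.flux_model <- function(x, ...) {
  cat(sprintf("flux_model: %d metabolites x %d reactions (%d designated exchange)\n",
              nrow(x$S), ncol(x$S), length(x$exchange_ids)))
  invisible(x)
}

#' @export
dim.flux_model <- function(x) dim(x$S)

#' Read a stoichiometric model from a tab-separated table
#'
#' The file layout is: a header row of reaction ids, a first column of
#' metabolite ids, and a numeric body of stoichiometric coefficients
#' (production-positive).
#'
#' @param path path to a TSV model file.
#' @return A [flux_model()].
#' @seealso [write_flux_model()] for the inverse operation.
#' @export
read_flux_model <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("model table needs an id column plus at least one reaction column")
  ids <- as.character(tab[[1]])
  body <- tab[, -1, drop = FALSE]
  numeric_cols <- vapply(body, is.numeric, logical(1))
  if (!all(numeric_cols)) {
    stop("non-numeric cells in reaction column(s): ",
         paste(names(body)[!numeric_cols], collapse = ", "))
  }
  S <- as.matrix(body)
  rownames(S) <- ids
  flux_model(S)
}

#' Write a stoichiometric model to a tab-separated table
#'
#' @param model a [flux_model()].
#' @param path output path.  `read_flux_model(write_flux_model(m, p))`
#'   round-trips the numeric table exactly.
#' @return `path`, invisibly.
#' @export
write_flux_model <- function(model, path) {
  stopifnot(inherits(model, "flux_model"))
  df <- data.frame(metabolite = model$metabolite_ids, model$S,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an exchange-flux measurement table
#'
#' CSV with header `reaction_id,value,sd`: one row per measured exchange
#' flux, with its value and measurement standard deviation (same units,
#' e.g. nmol/1e6 cells/h).
#'
#' @param path path to the CSV file.
#' @return A data frame with columns `reaction_id`, `value`, `sd`.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("reaction_id", "value", "sd")
  if (!all(required %in% names(df))) {
    stop("measurement file must have columns ", paste(required, collapse = ", "))
  }
  df$reaction_id <- as.character(df$reaction_id)
  if (anyDuplicated(df$reaction_id)) stop("duplicate measured reaction ids")
  if (!is.numeric(df$value) || !is.numeric(df$sd)) stop("value and sd must be numeric")
  if (any(df$sd < 0)) stop("measurement sd must be nonnegative")
  df[required]
}

#' Read a candidate-reaction stoichiometry table
#'
#' Same TSV dialect as the model file.  Rows must match the model's
#' metabolites; by default every model metabolite must be present (strict
#' row match).  With `allow_missing_rows = TRUE`, metabolites absent from
#' the file get zero coefficients.
#'
#' @param path path to the candidate TSV.
#' @param model the [flux_model()] whose metabolite ordering the candidate
#'   block must follow.
#' @param allow_missing_rows treat missing metabolite rows as zeros.
#' @return A numeric matrix with one column per candidate reaction, rows
#'   aligned to `model$metabolite_ids`.
#' @export
read_reaction_block <- function(path, model, allow_missing_rows = FALSE) {
  stopifnot(inherits(model, "flux_model"))
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate metabolite ids in candidate table")
  unknown <- setdiff(ids, model$metabolite_ids)
  if (length(unknown)) stop("candidate table has metabolites absent from the model: ",
                            paste(unknown, collapse = ", "))
  missing <- setdiff(model$metabolite_ids, ids)
  if (length(missing) && !allow_missing_rows) {
    stop("candidate table is missing metabolite row(s): ",
         paste(missing, collapse = ", "),
         " (set allow_missing_rows = TRUE to treat them as zero)")
  }
  body <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(body)) stop("non-numeric cells in candidate table")
  Z <- matrix(0, nrow = nrow(model$S), ncol = ncol(body),
              dimnames = list(model$metabolite_ids, colnames(body)))
  Z[ids, ] <- body
  Z
}

#' Numerical estimability (rank) report
#'
#' Computes the numerical rank of a matrix from its singular values.  Flux
#' estimation requires the internal stoichiometry to have full column rank;
#' this report says whether that holds at the given tolerance.
#'
#' @param M numeric matrix (non-empty).
#' @param tolerance singular-value threshold; default
#'   `max(dim(M)) * .Machine$double.eps * max(singular values)`.
#' @return An object of class `rank_report` with fields `numerical_rank`,
#'   `n_columns`, `singular_values`, `tolerance` and `is_estimable`
#'   (`TRUE` iff `numerical_rank == n_columns`).
#' @export
check_estimability <- function(M, tolerance = NULL) {
  M <- as.matrix(M)
  if (length(M) == 0) stop("empty matrix")
  r <- svd_rank(M, tolerance)
  structure(list(numerical_rank = r$rank,
                 n_columns = ncol(M),
                 singular_values = r$singular_values,
                 tolerance = r$tolerance,
                 is_estimable = r$rank == ncol(M)),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("rank_report: numerical rank %d of %d columns (tolerance %.3g) -> %s\n",
              x$numerical_rank, x$n_columns, x$tolerance,
              if (x$is_estimable) "estimable" else "NOT estimable"))
  invisible(x)
}

#' Partition a model into measured-exchange and internal blocks
#'
#' Splits the stoichiometric matrix column-wise into `S_E` (the measured
#' exchange reactions, in measurement order) and `S_I` (the remaining
#' internal reactions, in model order), and attaches the measured flux
#' values `v_E` and their standard deviations.  `cbind(S_E, S_I)` is a
#' column permutation of the parent matrix.
#'
#' @param model a [flux_model()].
#' @param measurements data frame with columns `reaction_id`, `value`, `sd`
#'   (see [read_measurements()]).
#' @param tolerance rank tolerance forwarded to [check_estimability()].
#' @return An object of class `partitioned_model` with elements `S_E`,
#'   `S_I`, `v_E`, `sd_E`, `exchange_ids`, `internal_ids`,
#'   `metabolite_ids`.
#' @export
partition_model <- function(model, measurements, tolerance = NULL) {
  stopifnot(inherits(model, "flux_model"))
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  ids <- as.character(measurements$reaction_id)
  unknown <- setdiff(ids, model$reaction_ids)
  if (length(unknown)) stop("measured reaction id(s) not in model: ",
                            paste(unknown, collapse = ", "))
  if (any(measurements$sd < 0)) stop("measurement sd must be nonnegative")
  internal <- setdiff(model$reaction_ids, ids)
  if (length(internal) == 0) {
    stop("estimability error: all reactions are measured, nothing to estimate")
  }
  S_E <- model$S[, ids, drop = FALSE]
  S_I <- model$S[, internal, drop = FALSE]
  rep_ <- check_estimability(S_I, tolerance)
  if (!rep_$is_estimable) {
    stop(sprintf(paste0("estimability error: internal stoichiometry S_I is rank ",
                        "deficient (numerical rank %d of %d columns, tolerance %.3g)"),
                 rep_$numerical_rank, rep_$n_columns, rep_$tolerance))
  }
  structure(list(S_E = S_E, S_I = S_I,
                 v_E = stats::setNames(as.numeric(measurements$value), ids),
                 sd_E = stats::setNames(as.numeric(measurements$sd), ids),
                 exchange_ids = ids, internal_ids = internal,
                 metabolite_ids = model$metabolite_ids,
                 rank_report = rep_),
            class = "partitioned_model")
}

#' @export
print.partitioned_model <- function(x, ...) {
  cat(sprintf("partitioned_model: %d metabolites, %d measured exchanges, %d internal fluxes\n",
              length(x$metabolite_ids), length(x$exchange_ids), length(x$internal_ids)))
  invisible(x)
}

#' Remove reactions from a model
#'
#' @param model a [flux_model()].
#' @param ids reaction ids to remove (subset of `model$reaction_ids`).
#' @param forbid_orphans reject removals that leave any metabolite with an
#'   all-zero row (the default; model reduction for flux analysis should
#'   not strand a species).
#' @return The reduced [flux_model()]; coefficients of retained columns are
#'   unchanged.
#' @export
remove_reactions <- function(model, ids, forbid_orphans = TRUE) {
  stopifnot(inherits(model, "flux_model"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, model$reaction_ids)
  if (length(unknown)) stop("cannot remove unknown reaction id(s): ",
                            paste(unknown, collapse = ", "))
  if (length(ids) == 0) return(model)
  keep <- setdiff(model$reaction_ids, ids)
  if (length(keep) == 0) stop("removal would empty the model")
  S <- model$S[, keep, drop = FALSE]
  orphans <- rowSums(S != 0) == 0
  if (any(orphans) && forbid_orphans) {
    stop("removal would orphan species ",
         paste(model$metabolite_ids[orphans], collapse = ", "))
  }
  flux_model(S, exchange = intersect(model$exchange_ids, keep),
             allow_orphans = TRUE)
}
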