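#' LFQ dataset container
#'
#' The pipeline's central carrier: a proteins x runs intensity matrix on the
#' raw label-free quantification (LFQ) scale (or log2 of it), together with
#' per-run metadata and per-protein identification flags. Missing
#' observations are stored as `NA`, which keeps them distinct from a measured
#' zero; raw MaxQuant-style exports encode non-observation as 0 and the
#' zero-removal filter ([drop_zero_observations()]) is the step that turns
#' those into `NA`.
#'
#' @param intensity numeric matrix, proteins in rows, runs in columns.
#'   Rownames must be protein ids, colnames run ids. Non-negative on the raw
#'   scale; `NA` marks a missing observation.
#' @param runs data.frame of run metadata with columns `run_id`,
#'   `genetic_context`, `culture_context`, `concentration`, `bio_rep`,
#'   `tech_rep`, `is_control`. One row per intensity column, same order.
#' @param proteins data.frame with columns `protein_id`, `gene_name`,
#'   `flag_site_only`, `flag_contaminant`, `flag_reverse`. One row per
#'   intensity row, same order.
#' @param log2_scale logical; `TRUE` if `intensity` holds log2-transformed
#'   values.
#'
#' @return An object of class `lfq_dataset`.
#' @export
lfq_dataset <- function(intensity, runs, proteins, log2_scale = FALSE) {
  stopifnot(is.matrix(intensity), is.data.frame(runs), is.data.frame(proteins))
  if (nrow(intensity) != nrow(proteins))
    stop("intensity rows (", nrow(intensity), ") != proteins (", nrow(proteins), ")")
  if (ncol(intensity) != nrow(runs))
    stop("intensity cols (", ncol(intensity), ") != runs (", nrow(runs), ")")
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]), collapse = ", "))
  if (anyDuplicated(runs$run_id)) stop("duplicate run_id")
  rownames(intensity) <- proteins$protein_id
  colnames(intensity) <- runs$run_id
  runs$run_id <- as.character(runs$run_id)
  validate_run_meta(runs)
  structure(
    list(intensity = intensity, runs = runs, proteins = proteins,
         log2_scale = isTRUE(log2_scale)),
    class = "lfq_dataset"
  )
}

GENETIC_LEVELS     <- c("WT", "G12D", "G12V", "G12C")
CULTURE_LEVELS     <- c("unstim", "DMOG", "EGF", "IL6", "PGE2", "TNFa")
CONCENTRATION_LEVELS <- c("none", "20", "200")
CONTROL_SENTINEL   <- "ctrl"

validate_run_meta <- function(runs) {
  need <- c("run_id", "genetic_context", "culture_context", "concentration",
            "bio_rep", "tech_rep", "is_control")
  miss <- setdiff(need, names(runs))
  if (length(miss)) stop("run metadata missing columns: ", paste(miss, collapse = ", "))
  smp <- runs[!runs$is_control, , drop = FALSE]
  if (nrow(smp)) {
    bad <- !smp$genetic_context %in% GENETIC_LEVELS
    if (any(bad)) stop("unknown genetic_context: ", unique(smp$genetic_context[bad])[1])
    bad <- !smp$culture_context %in% CULTURE_LEVELS
    if (any(bad)) stop("unknown culture_context: ", unique(smp$culture_context[bad])[1])
    bad <- !as.character(smp$concentration) %in% CONCENTRATION_LEVELS
    if (any(bad)) stop("unknown concentration: ", unique(smp$concentration[bad])[1])
    # unstimulated growth has no added stimulus concentration, and vice versa
    un <- smp$culture_context == "unstim"
    if (any(un != (as.character(smp$concentration) == "none")))
      stop("culture_context 'unstim' must pair with concentration 'none' (and only then)")
    key <- do.call(paste, c(smp[c("genetic_context", "culture_context",
                                  "concentration", "bio_rep", "tech_rep")], sep = "\r"))
    if (anyDuplicated(key)) stop("duplicate (context, replicate) combination in run metadata")
  }
  invisible(runs)
}

#' @export
print.lfq_dataset <- function(x, ...) {
  cat(sprintf("lfq_dataset: %d proteins x %d runs (%d control), %s scale, %.1f%% missing\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$runs$is_control),
              if (x$log2_scale) "log2" else "raw",
              100 * mean(is.na(x$intensity))))
  invisible(x)
}

#' @export
dim.lfq_dataset <- function(x) dim(x$intensity)

#' Condition label for each run
#'
#' A condition is the (genetic context, culture context, concentration)
#' triple; bead-only control runs are labelled with the control sentinel.
#'
#' @param runs run metadata data.frame (or an `lfq_dataset`).
#' @return character vector of condition labels, one per run.
#' @export
condition_of <- function(runs) {
  if (inherits(runs, "lfq_dataset")) runs <- runs$runs
  ifelse(runs$is_control, CONTROL_SENTINEL,
         paste(runs$genetic_context, runs$culture_context,
               runs$concentration, sep = "."))
}

#' Subset an LFQ dataset
#'
#' @param ds an `lfq_dataset`.
#' @param proteins,runs logical/integer/character index into the protein and
#'   run dimension; `NULL` keeps all.
#' @return the subset `lfq_dataset`.
#' @export
subset_lfq <- function(ds, proteins = NULL, runs = NULL) {
  pi <- if (is.null(proteins)) seq_len(nrow(ds$intensity)) else proteins
  ri <- if (is.null(runs)) seq_len(ncol(ds$intensity)) else runs
  if (is.character(pi)) {
    pi <- match(pi, ds$proteins$protein_id)
    if (anyNA(pi)) stop("unknown protein_id in subset")
  }
  if (is.character(ri)) {
    ri <- match(ri, ds$runs$run_id)
    if (anyNA(ri)) stop("unknown run_id in subset")
  }
  lfq_dataset(ds$intensity[pi, ri, drop = FALSE],
              ds$runs[ri, , drop = FALSE],
              ds$proteins[pi, , drop = FALSE],
              log2_scale = ds$log2_scale)
}

#' Log2-transform the intensity matrix
#'
#' Observed raw intensities are log2-transformed; `NA` stays `NA`. Raw zeros
#' (possible before zero removal) map to `NA` with a warning, since log2(0)
#' is undefined.
#'
#' @param ds an `lfq_dataset` on the raw scale.
#' @return the dataset with `log2_scale = TRUE`.
#' @export
log2_transform <- function(ds) {
  if (ds$log2_scale) return(ds)
  m <- ds$intensity
  z <- !is.na(m) & m == 0
  if (any(z)) {
    warning(sum(z), " zero cells set to NA during log2 transform; ",
            "run drop_zero_observations() first")
    m[z] <- NA_real_
  }
  ds$intensity <- log2(m)
  ds$log2_scale <- TRUE
  ds
}
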