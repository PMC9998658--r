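#' The condition grid of a context-specific AP-MS experiment
#'
#' Enumerates the experimental conditions: every genetic context (bait
#' variant) crossed with every culture context, where the unstimulated
#' medium has no added stimulus and each stimulus is applied at each listed
#' concentration. With the defaults (4 genetic contexts; unstimulated plus 5
#' stimuli at 2 concentrations = 11 culture contexts) this gives 44
#' conditions and, at 3 biological x 2 technical replicates, 264 MS runs.
#'
#' @param genetic character vector of genetic contexts.
#' @param stimuli character vector of stimulus culture contexts.
#' @param concentrations character vector of stimulus concentrations (ng/ml).
#' @param include_unstim include the unstimulated (no-stimulus) context.
#' @param n_bio,n_tech biological and technical replicates per condition.
#' @return list with `conditions` (data.frame `genetic_context`,
#'   `culture_context`, `concentration`), `n_conditions` and `n_runs`.
#' @export
#' @examples
#' g <- design_grid()
#' g$n_conditions  # 44
#' g$n_runs        # 264
design_grid <- function(genetic = GENETIC_LEVELS,
                        stimuli = setdiff(CULTURE_LEVELS, "unstim"),
                        concentrations = c("20", "200"),
                        include_unstim = TRUE,
                        n_bio = 3, n_tech = 2) {
  cc <- expand.grid(culture_context = stimuli,
                    concentration = concentrations,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (include_unstim)
    cc <- rbind(data.frame(culture_context = "unstim", concentration = "none",
                           stringsAsFactors = FALSE), cc)
  conditions <- merge(data.frame(genetic_context = genetic,
                                 stringsAsFactors = FALSE), cc, by = NULL)
  conditions <- conditions[order(conditions$genetic_context,
                                 conditions$culture_context,
                                 conditions$concentration), , drop = FALSE]
  rownames(conditions) <- NULL
  list(conditions = conditions,
       n_conditions = nrow(conditions),
       n_runs = as.integer(nrow(conditions) * n_bio * n_tech),
       n_bio = n_bio, n_tech = n_tech)
}

#' Overlap of an identified interactome with a literature set
#'
#' Given the number of identified high-confidence interactors, the size of a
#' previously reported (literature) interactome, and their intersection,
#' reports the percentage of the literature set recovered and the number of
#' identified proteins that are novel (not previously reported).
#'
#' @param n_identified number of identified interactors.
#' @param n_literature size of the literature set.
#' @param n_overlap size of the intersection.
#' @return list with `pct_literature_recovered` (percent, one decimal's
#'   worth of precision retained as a plain number) and `n_novel`.
#' @export
#' @examples
#' overlap_report(2265, 811, 245)  # 30.2% of literature, 2020 novel
overlap_report <- function(n_identified, n_literature, n_overlap) {
  if (n_overlap > min(n_identified, n_literature))
    stop("overlap larger than one of the sets")
  list(pct_literature_recovered = 100 * n_overlap / n_literature,
       n_novel = n_identified - n_overlap)
}
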