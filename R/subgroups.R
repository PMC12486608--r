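#' Select contrasts for a metadata-defined subgroup
#'
#' `female_only` keeps contrasts whose sample is flagged female-only;
#' `adolescent` and `adult` filter on the age group; `all` is the
#' identity. Contrasts with unknown metadata are excluded from the
#' subgroup (never imputed) and listed in the `dropped` attribute.
#'
#' @param contrasts named list of [StudyContrast-class] objects.
#' @param criterion one of `"female_only"`, `"adolescent"`, `"adult"`,
#'   `"all"`.
#' @return The selected sublist, with attribute `dropped` (character
#'   ids). An empty selection is an error naming the criterion.
#' @export
selectContrasts <- function(contrasts,
                            criterion = c("all", "female_only",
                                          "adolescent", "adult")) {
  criterion <- match.arg(criterion)
  keep <- vapply(contrasts, function(sc) {
    switch(criterion,
           all = TRUE,
           female_only = isTRUE(sc@sexFemaleOnly),
           adolescent = identical(sc@ageGroup, "adolescent"),
           adult = identical(sc@ageGroup, "adult"))
  }, logical(1))
  if (!any(keep))
    stop("subgroup '", criterion, "' selects no contrast")
  out <- contrasts[keep]
  attr(out, "dropped") <- names(contrasts)[!keep]
  out
}

#' Run the pipeline on each metadata-defined subgroup
#'
#' Executes an independent full pipeline per subgroup; each subgroup's
#' probability map uses its own contrast count as denominator. Empty
#' subgroups are skipped with a warning rather than aborting the suite.
#' Runs are pure functions of their inputs, so the main (`all`) run is
#' unaffected by whichever subgroups execute alongside it.
#'
#' @inheritParams runFCNM
#' @param criteria subgroups to run (default the three standard ones
#'   plus `all`).
#' @param ... passed to [runFCNM()].
#' @return Named list of [runFCNM()] results, one per non-empty
#'   criterion; each carries `subgroup` and `droppedContrasts`.
#' @export
runSubgroupSuite <- function(contrasts, subjects, brain,
                             criteria = c("all", "female_only",
                                          "adolescent", "adult"),
                             ...) {
  out <- list()
  for (cr in criteria) {
    sel <- tryCatch(selectContrasts(contrasts, cr),
                    error = function(e) NULL)
    if (is.null(sel)) {
      warning("skipping subgroup '", cr, "': no matching contrast",
              call. = FALSE)
      next
    }
    res <- runFCNM(sel, subjects, brain, ...)
    res$subgroup <- cr
    res$droppedContrasts <- attr(sel, "dropped")
    out[[cr]] <- res
  }
  if (!length(out)) stop("every requested subgroup was empty")
  out
}
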