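#' Stratify subjects into ABA / RBA / MIXED by BrainAGE sign
#'
#' A subject is accelerated brain aging (ABA) when BrainAGE is strictly
#' positive in all three modalities, resilient (RBA) when strictly negative
#' in all three, and MIXED otherwise; an exact zero in any modality maps to
#' MIXED (the sign rule is strict).
#'
#' @param brainage_smri,brainage_dmri,brainage_rsfmri aligned BrainAGE
#'   vectors (years). If named, names must agree across the three vectors and
#'   are used as subject IDs.
#' @param ids optional subject identifiers (overrides names).
#' @return a data.frame of class `stratification_result` with columns
#'   `subject_id`, `brainage_sMRI`, `brainage_dMRI`, `brainage_rsfMRI`,
#'   `group` (factor ABA/RBA/MIXED).
#' @export
stratify <- function(brainage_smri, brainage_dmri, brainage_rsfmri, ids = NULL) {
  n <- length(brainage_smri)
  if (length(brainage_dmri) != n || length(brainage_rsfmri) != n) {
    stopf("alignment_error", "BrainAGE vectors have different lengths")
  }
  nm <- list(names(brainage_smri), names(brainage_dmri), names(brainage_rsfmri))
  has_nm <- !vapply(nm, is.null, logical(1))
  if (any(has_nm)) {
    if (!all(has_nm) || !identical(nm[[1]], nm[[2]]) || !identical(nm[[1]], nm[[3]])) {
      stopf("alignment_error", "subject IDs differ across modalities")
    }
    if (is.null(ids)) ids <- nm[[1]]
  }
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
  group <- rep("MIXED", n)
  group[brainage_smri > 0 & brainage_dmri > 0 & brainage_rsfmri > 0] <- "ABA"
  group[brainage_smri < 0 & brainage_dmri < 0 & brainage_rsfmri < 0] <- "RBA"
  out <- data.frame(subject_id = as.character(ids),
                    brainage_sMRI = as.numeric(brainage_smri),
                    brainage_dMRI = as.numeric(brainage_dmri),
                    brainage_rsfMRI = as.numeric(brainage_rsfmri),
                    group = factor(group, levels = c("ABA", "RBA", "MIXED")),
                    stringsAsFactors = FALSE)
  class(out) <- c("stratification_result", "data.frame")
  out
}

#' Group counts of a stratification
#' @param result a `stratification_result`.
#' @return named integer vector with entries ABA, RBA, MIXED summing to the
#'   number of subjects.
#' @export
stratification_summary <- function(result) {
  stopifnot(inherits(result, "stratification_result"))
  counts <- table(result$group)
  stats::setNames(as.integer(counts), names(counts))
}

#' @export
print.stratification_result <- function(x, ...) {
  counts <- stratification_summary(x)
  cat(sprintf("stratification of %d subjects: ABA %d, RBA %d, MIXED %d\n",
              nrow(x), counts[["ABA"]], counts[["RBA"]], counts[["MIXED"]]))
  invisible(x)
}
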