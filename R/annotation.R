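# Mass-based annotation of discriminatory components: peptides at relative
# tolerance against observed MH+ masses, lipids at absolute tolerance with
# [M+H]+/[M+Na]+/[M+K]+ adduct expansion and lowest-delta best hits.

# cation masses minus one electron (Da)
ADDUCT_SHIFT <- c(H = 1.007276, Na = 22.989218, K = 38.963158)

#' Adduct m/z of a neutral mass
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct `"H"`, `"Na"` or `"K"`.
#' @return Observed m/z: mass plus the cation mass minus one electron.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) abort_msi("neutral mass must be > 0")
  adduct <- as.character(adduct)
  if (!all(adduct %in% names(ADDUCT_SHIFT)))
    abort_msi("unknown adduct: ", paste(setdiff(adduct, names(ADDUCT_SHIFT)),
                                        collapse = ", "))
  unname(neutral_mass + ADDUCT_SHIFT[adduct])
}

annotation_frame <- function(component_mz, candidate_id, adduct,
                             theoretical_mz, class_label = NA_character_) {
  n <- length(component_mz)
  data.frame(component_mz = component_mz, candidate_id = candidate_id,
             adduct = rep_len(adduct, n),
             theoretical_mz = theoretical_mz,
             delta = component_mz - theoretical_mz,
             class_label = rep_len(class_label, n),
             is_best_hit = rep_len(FALSE, n), stringsAsFactors = FALSE)
}

flag_best_hits <- function(records, tie_order = c("none", "H", "Na", "K")) {
  if (!nrow(records)) return(records)
  records$is_best_hit <- FALSE
  for (mz in unique(records$component_mz)) {
    i <- which(records$component_mz == mz)
    o <- i[order(abs(records$delta[i]),
                 match(records$adduct[i], tie_order),
                 records$candidate_id[i])]
    records$is_best_hit[o[1]] <- TRUE
  }
  records
}

#' Match component m/z values against peptide candidates
#'
#' Candidate masses are observed singly protonated (MH+) masses; a
#' candidate matches when `|candidate - component| <= 0.0005 x component`
#' (+-0.05% relative tolerance, window closed). All matches are retained;
#' the best hit per component has the lowest |delta|.
#'
#' @param components Numeric component m/z values.
#' @param candidates A [candidate_mass_list()] of kind `"peptide"`.
#' @return Data frame of annotation records (possibly zero rows):
#'   `component_mz`, `candidate_id`, `adduct` (`"none"`),
#'   `theoretical_mz`, `delta`, `is_best_hit`.
#' @export
match_peptide_masses <- function(components, candidates) {
  cand <- candidates[candidates$kind == "peptide", , drop = FALSE]
  out <- list()
  for (mz in components) {
    tol <- 5e-4 * mz
    hit <- which(abs(cand$mass - mz) <= tol)
    if (length(hit))
      out[[length(out) + 1L]] <- annotation_frame(
        rep(mz, length(hit)), cand$id[hit], "none", cand$mass[hit])
  }
  if (!length(out)) return(annotation_frame(numeric(0), character(0),
                                            character(0), numeric(0)))
  flag_best_hits(do.call(rbind, out))
}

#' Match component m/z values against lipid candidates with adducts
#'
#' Each neutral candidate mass is expanded to its `[M+H]+`, `[M+Na]+` and
#' `[M+K]+` m/z; matches fall within the absolute tolerance (default 0.5 Da,
#' window closed). The best hit per component has the lowest |delta|; ties
#' prefer the lighter adduct (H < Na < K), then the candidate id.
#'
#' @param components Numeric component m/z values.
#' @param candidates A [candidate_mass_list()] of kind `"lipid"` (neutral
#'   masses).
#' @param tol Absolute tolerance in Da (default 0.5).
#' @return Data frame of annotation records as in
#'   [match_peptide_masses()], with `adduct` in H/Na/K and the candidate's
#'   `class_label`.
#' @export
match_lipid_masses <- function(components, candidates, tol = 0.5) {
  cand <- candidates[candidates$kind == "lipid", , drop = FALSE]
  adducts <- names(ADDUCT_SHIFT)
  out <- list()
  for (mz in components) {
    for (ad in adducts) {
      theo <- cand$mass + ADDUCT_SHIFT[[ad]]
      hit <- which(abs(theo - mz) <= tol)
      if (length(hit))
        out[[length(out) + 1L]] <- annotation_frame(
          rep(mz, length(hit)), cand$id[hit], ad, theo[hit],
          cand$class_label[hit])
    }
  }
  if (!length(out)) return(annotation_frame(numeric(0), character(0),
                                            character(0), numeric(0)))
  flag_best_hits(do.call(rbind, out))
}
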