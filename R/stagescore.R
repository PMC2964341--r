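#' Nucleoplasmic fraction of nuclear-phenotype cells in a well
#'
#' For the Rps2-YFP readout, the ratio of nucleoplasmic-classified cells to
#' all hit-classified cells (nucleolar plus nucleoplasmic). A value of 0
#' means every hit-classified cell is nucleolar (early, intranucleolar
#' defect); 1 means every one is nucleoplasmic (late nuclear defect, e.g. a
#' blocked export step). Wells without nuclear-phenotype cells have no
#' defined ratio and propagate as `NA`, never 0.
#'
#' @param wells Rps2 per-well data.frame with `nucleolar_count` and
#'   `nucleoplasmic_count`
#' @return `wells` with a `np_ratio` column
#' @export
nucleoplasmic_ratio <- function(wells) {
  stopifnot(all(c("nucleolar_count", "nucleoplasmic_count") %in% names(wells)))
  denom <- wells$nucleolar_count + wells$nucleoplasmic_count
  out <- wells
  out$np_ratio <- ifelse(denom > 0, wells$nucleoplasmic_count / denom,
                         NA_real_)
  out
}

#' Per-target stage score along the nuclear 40S maturation pathway
#'
#' For each target, the stage score is the mean nucleoplasmic ratio of the
#' two siRNAs with the highest hit rates (selection by hit rate, not by
#' rank), and the quality measure is the absolute difference between those
#' two siRNAs' ratios — concordant siRNAs give quality near 0. Targets
#' with fewer than two defined ratios are reported not evaluable.
#'
#' @param wells Rps2 per-well data.frame with `np_ratio` (see
#'   [nucleoplasmic_ratio()]) and `hit_rate`
#' @return data.frame per target: score in [0,1], quality in [0,1],
#'   evaluable flag
#' @export
target_stage_score <- function(wells) {
  stopifnot("np_ratio" %in% names(wells))
  samp <- wells[wells$role == "sample" & !is.na(wells$target), , drop = FALSE]
  out <- lapply(split(samp, samp$target), function(df) {
    ok <- df[!is.na(df$np_ratio), , drop = FALSE]
    if (nrow(ok) < 2) {
      return(data.frame(target = df$target[1], score = NA_real_,
                        quality = NA_real_, evaluable = FALSE,
                        stringsAsFactors = FALSE))
    }
    top <- ok[order(-ok$hit_rate, ok$sirna), ][1:2, ]
    data.frame(target = df$target[1],
               score = mean(top$np_ratio),
               quality = abs(diff(top$np_ratio)),
               evaluable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cytoplasmic-maturation call from the Rio2 +LMB readout
#'
#' Rio2 recycles to the nucleus through the Crm1 pathway; under leptomycin B
#' (LMB) it is trapped in the nucleus unless stuck on cytoplasmic pre-40S
#' particles. A target is called a cytoplasmic-maturation hit when more
#' than 20 percent of cells keep cytoplasmic Rio2 after LMB: the statistic
#' is the mean of the two highest per-siRNA fractions (or the single
#' available fraction, flagged as single-siRNA support).
#'
#' @param fractions named numeric vector (or data.frame with `target`,
#'   `sirna`, `fraction`) of per-siRNA cytoplasmic-Rio2-after-LMB fractions
#'   for one target
#' @param threshold call threshold (default 0.20, strict)
#' @return list: statistic, hit flag, single_sirna flag, n_sirnas
#' @export
rio2_lmb_call <- function(fractions, threshold = 0.20) {
  f <- if (is.data.frame(fractions)) fractions$fraction else as.numeric(fractions)
  if (!length(f)) stop("at least one siRNA fraction is required")
  if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
  srt <- sort(f, decreasing = TRUE)
  statistic <- if (length(srt) >= 2) mean(srt[1:2]) else srt[1]
  list(statistic = statistic, hit = statistic > threshold,
       single_sirna = length(f) == 1, n_sirnas = length(f))
}

#' Group a ribosomal-protein target by its readout phenotype combination
#'
#' Sorts a target into the nuclear/cytoplasmic requirement taxonomy from
#' the combined Rps2-YFP, Enp1 IF and Rio2 IF (+LMB) readouts:
#' \itemize{
#'   \item nuclear, Rps2 only (`nuclear_rps2_only`)
#'   \item nuclear, Rps2 and nuclear Enp1 (`nuclear_both`)
#'   \item cytoplasmic by Enp1 (`cytoplasmic_enp1`), by Rio2
#'     (`cytoplasmic_rio2`), or both (`cytoplasmic_both`; these may also
#'     show nuclear Rps2 accumulation)
#'   \item mixed nuclear Rps2 + cytoplasmic Rio2 without cytoplasmic Enp1
#'     (`mixed`)
#' }
#' Targets with no flag in any readout return `NA` (absent from grouping).
#'
#' @param rps2_hit nuclear Rps2-YFP high-confidence hit flag
#' @param enp1_nuclear_hit nuclear (nucleoplasmic) Enp1 hit flag
#' @param enp1_cytoplasmic_hit cytoplasmic Enp1 hit flag
#' @param rio2_hit Rio2 +LMB cytoplasmic hit flag
#' @return one of `"nuclear_rps2_only"`, `"nuclear_both"`,
#'   `"cytoplasmic_enp1"`, `"cytoplasmic_rio2"`, `"cytoplasmic_both"`,
#'   `"mixed"`, or `NA_character_`
#' @export
rps_grouping <- function(rps2_hit, enp1_nuclear_hit,
                         enp1_cytoplasmic_hit, rio2_hit) {
  stopifnot(is.logical(rps2_hit), is.logical(enp1_nuclear_hit),
            is.logical(enp1_cytoplasmic_hit), is.logical(rio2_hit))
  if (enp1_cytoplasmic_hit && rio2_hit) return("cytoplasmic_both")
  if (rps2_hit && rio2_hit) return("mixed")
  if (rps2_hit && enp1_nuclear_hit) return("nuclear_both")
  if (rps2_hit) return("nuclear_rps2_only")
  if (enp1_cytoplasmic_hit) return("cytoplasmic_enp1")
  if (rio2_hit) return("cytoplasmic_rio2")
  NA_character_
}
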