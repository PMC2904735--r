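#' Label screen-positive regulators from Z-scores
#'
#' A gene is a screen-positive regulator (SPR) when its screen Z-score is
#' strictly below `-threshold` or strictly above `threshold` -- siRNAs with
#' some impact on the phenotype in either direction.  Genes with a missing
#' Z-score (not screened, e.g. network proteins outside the siRNA library)
#' are not SPRs.  The known-regulator (KPR) flag is carried through
#' unchanged.
#'
#' @param annotations data.frame from [readAnnotations()] (columns `id`,
#'   `z_score`, `is_kpr`).
#' @param threshold positive Z-score cutoff (default 1; ties excluded).
#' @return data.frame `id`, `z_score`, `is_spr`, `is_kpr`, one row per input
#'   row, plus attributes `sprs`, `kprs`, `overlap` (identifier vectors).
#' @examples
#' ann <- data.frame(id = c("EDNRB", "EDN3", "GNA11"),
#'                   z_score = c(-1.1, 0.2, -1.9),
#'                   is_kpr = c(TRUE, TRUE, FALSE))
#' labels <- labelSPRs(ann)
#' labels$is_spr   # TRUE FALSE TRUE
#' @export
labelSPRs <- function(annotations, threshold = 1.0) {
  if (threshold <= 0) stop("threshold must be > 0")
  z <- annotations$z_score
  spr <- !is.na(z) & (z < -threshold | z > threshold)
  out <- data.frame(id = annotations$id, z_score = z,
                    is_spr = spr, is_kpr = annotations$is_kpr,
                    stringsAsFactors = FALSE)
  attr(out, "sprs") <- out$id[spr]
  attr(out, "kprs") <- out$id[out$is_kpr]
  attr(out, "overlap") <- out$id[spr & out$is_kpr]
  out
}

#' Normalized percent inhibition of a pigment assay
#'
#' Pigment indices are absorbance at 405 nm divided by luminescence (the
#' latter proportional to cell number), giving relative pigment per cell.
#' The normalized percent inhibition rescales a sample between the
#' non-targeting negative control (0%) and the tyrosinase positive control
#' (100%):
#' \deqn{NPI = \frac{neg - sample}{neg - tyr} \times 100}
#'
#' @param sample,negControl,tyrControl pigment indices (unitless ratios);
#'   vectors recycle in the usual way.
#' @return Percent inhibition (can fall outside `[0, 100]` for samples more
#'   extreme than the controls).
#' @examples
#' normalizedPercentInhibition(0.6, negControl = 1.0, tyrControl = 0.2)  # 50
#' @export
normalizedPercentInhibition <- function(sample, negControl, tyrControl) {
  if (any(negControl == tyrControl))
    stop("negative and tyrosinase control indices coincide; ",
         "controls are uninformative")
  (negControl - sample) / (negControl - tyrControl) * 100
}

#' Compute a pigment index
#'
#' @param absorbance absorbance at 405 nm.
#' @param luminescence raw luminescence (> 0), proportional to cell number.
#' @return Relative pigment per cell (absorbance / luminescence).
#' @export
pigmentIndex <- function(absorbance, luminescence) {
  if (any(luminescence <= 0)) stop("luminescence must be > 0")
  absorbance / luminescence
}

#' Write screen labels as TSV
#'
#' Columns `id`, `is_spr`, `is_kpr`, `z_score`, lexicographic by id.
#'
#' @param labels data.frame from [labelSPRs()].
#' @param path output file path.
#' @export
writeScreenLabels <- function(labels, path) {
  df <- labels[order(labels$id), c("id", "is_spr", "is_kpr", "z_score")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
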