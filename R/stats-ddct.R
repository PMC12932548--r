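## Relative qPCR quantification by the delta-delta-Ct method with a
## reference gene and a calibrator condition.

#' Relative expression by the delta-delta-Ct method
#'
#' For every target gene and condition, `dCt = Ct_target - Ct_reference`;
#' against the calibrator condition, `ddCt = dCt_sample - dCt_calibrator`.
#' The value returned is `-ddCt`, so positive values indicate enhanced
#' expression relative to the calibrator (each unit is one cycle, i.e. a
#' factor of ~2 in expression: `fold_change = 2^(-ddCt)`).
#'
#' Replicate Ct values within a (condition, gene) cell are averaged before
#' differencing.
#'
#' @param ct `data.frame` with columns `condition`, `gene`, `ct`.
#' @param reference_gene Name of the reference (housekeeping) gene.
#' @param calibrator Name of the calibrator condition.
#' @return `data.frame` with columns `condition`, `gene`, `dct`,
#'   `minus_ddct`, `fold_change`, for every non-reference gene and every
#'   condition (the calibrator rows have `minus_ddct = 0`).
#' @export
delta_delta_ct <- function(ct, reference_gene, calibrator) {
  need <- c("condition", "gene", "ct")
  stop_if(!is.data.frame(ct) || !all(need %in% names(ct)),
          "`ct` needs columns condition, gene, ct")
  stop_if(!(reference_gene %in% ct$gene),
          "reference gene '%s' absent from the Ct table", reference_gene)
  stop_if(!(calibrator %in% ct$condition),
          "calibrator condition '%s' absent from the Ct table", calibrator)
  mean_ct <- stats::aggregate(ct ~ condition + gene, data = ct, FUN = mean)
  ref <- mean_ct[mean_ct$gene == reference_gene, c("condition", "ct")]
  names(ref)[2] <- "ct_ref"
  targets <- mean_ct[mean_ct$gene != reference_gene, , drop = FALSE]
  stop_if(nrow(targets) == 0, "no target genes in the Ct table")
  m <- merge(targets, ref, by = "condition", all.x = TRUE)
  stop_if(any(is.na(m$ct_ref)),
          "missing reference-gene Ct for condition(s): %s",
          paste(unique(m$condition[is.na(m$ct_ref)]), collapse = ", "))
  m$dct <- m$ct - m$ct_ref
  cal <- m[m$condition == calibrator, c("gene", "dct")]
  names(cal)[2] <- "dct_cal"
  stop_if(nrow(cal) == 0, "calibrator condition lacks target-gene Ct")
  m <- merge(m, cal, by = "gene", all.x = TRUE)
  stop_if(any(is.na(m$dct_cal)),
          "missing calibrator Ct for gene(s): %s",
          paste(unique(m$gene[is.na(m$dct_cal)]), collapse = ", "))
  m$minus_ddct <- -(m$dct - m$dct_cal)
  m$fold_change <- 2^m$minus_ddct
  out <- m[order(m$gene, m$condition),
           c("condition", "gene", "dct", "minus_ddct", "fold_change")]
  rownames(out) <- NULL
  out
}
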