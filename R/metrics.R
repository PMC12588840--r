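#' Dice similarity coefficient for one class
#'
#' `2|A n B| / (|A| + |B|)` over the binary masks of `class_id`. When both
#' masks are empty the score is defined as 1.0 (a perfectly predicted
#' absent class) and the result carries `attr(, "both_empty") = TRUE`.
#'
#' @param pred,ref [label_map()]s (or integer arrays) of equal shape.
#' @param class_id class in \{0,1,2,3\}.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(pred, ref, class_id) {
  m <- .class_masks(pred, ref, class_id)
  if (m$na == 0 && m$nb == 0) return(structure(1.0, both_empty = TRUE))
  2 * m$inter / (m$na + m$nb)
}

#' Jaccard index for one class
#'
#' `|A n B| / |A u B|`; both masks empty gives 1.0 (flagged).
#'
#' @inheritParams dice
#' @return JI in \[0, 1\].
#' @export
jaccard <- function(pred, ref, class_id) {
  m <- .class_masks(pred, ref, class_id)
  uni <- m$na + m$nb - m$inter
  if (uni == 0) return(structure(1.0, both_empty = TRUE))
  m$inter / uni
}

.class_masks <- function(pred, ref, class_id) {
  pl <- if (inherits(pred, "label_map")) pred$labels else pred
  rl <- if (inherits(ref, "label_map")) ref$labels else ref
  if (!identical(dim(pl), dim(rl))) {
    stop_validation("prediction and reference shapes differ", field = "pred")
  }
  if (!class_id %in% 0:3) {
    stop_validation("'class_id' must be in {0,1,2,3}", field = "class_id")
  }
  a <- pl == class_id
  b <- rl == class_id
  list(na = sum(a), nb = sum(b), inter = sum(a & b), a = a, b = b)
}

#' Symmetric Hausdorff distance for one class (physical units)
#'
#' Maximum over both directions of the max-min voxel-center distance
#' between the two class masks, in mm. Both masks empty gives 0; exactly
#' one empty gives NaN with `attr(, "undefined") = TRUE`.
#'
#' @inheritParams dice
#' @param spacing_mm voxel spacing along each axis (mm).
#' @return HD in mm.
#' @export
hausdorff <- function(pred, ref, class_id, spacing_mm = c(1, 1, 1)) {
  m <- .class_masks(pred, ref, class_id)
  if (m$na == 0 && m$nb == 0) return(0)
  if (m$na == 0 || m$nb == 0) return(structure(NaN, undefined = TRUE))
  A <- which(m$a, arr.ind = TRUE)
  B <- which(m$b, arr.ind = TRUE)
  cpp_hausdorff(A * 1.0, B * 1.0, as.numeric(spacing_mm))
}

#' Binned calibration input
#'
#' @param scores confidences (for ECE) or normalized uncertainties (for
#'   UCE), one per prediction, in \[0, 1\].
#' @param correct binary correctness indicator (1 = correct).
#' @param M number of equal-width bins partitioning \[0, 1\].
#' @return An object of class `calibration_input`.
#' @export
calibration_input <- function(scores, correct, M = 15L) {
  if (length(scores) != length(correct) || length(scores) == 0L) {
    stop_validation("'scores' and 'correct' must be equal-length, nonempty",
                    field = "scores")
  }
  if (any(scores < -1e-9) || any(scores > 1 + 1e-9)) {
    stop_validation("'scores' must lie in [0, 1]", field = "scores")
  }
  check_scalar_num(M, "M", min = 1)
  structure(list(scores = pmin(pmax(scores, 0), 1),
                 correct = as.numeric(correct != 0), M = as.integer(M),
                 n = length(scores)),
            class = "calibration_input")
}

.bin_table <- function(input) {
  M <- input$M
  bin <- pmin(floor(input$scores * M) + 1L, M)
  cnt <- tabulate(bin, nbins = M)
  ssum <- vapply(seq_len(M), function(m) sum(input$scores[bin == m]), 0)
  csum <- vapply(seq_len(M), function(m) sum(input$correct[bin == m]), 0)
  data.frame(bin = seq_len(M),
             center = (seq_len(M) - 0.5) / M,
             count = cnt,
             mean_score = ifelse(cnt > 0, ssum / cnt, NA_real_),
             accuracy = ifelse(cnt > 0, csum / cnt, NA_real_))
}

#' Expected calibration error
#'
#' Count-weighted mean absolute gap between per-bin accuracy and per-bin
#' mean confidence over M equal-width bins; empty bins contribute 0.
#'
#' @param input a [calibration_input()] whose scores are confidences.
#' @return ECE in \[0, 1\].
#' @export
ece <- function(input) {
  tb <- .bin_table(input)
  occ <- tb$count > 0
  sum(tb$count[occ] / input$n * abs(tb$accuracy[occ] - tb$mean_score[occ]))
}

#' Uncertainty calibration error
#'
#' Count-weighted mean absolute gap between per-bin error rate and per-bin
#' mean uncertainty score.
#'
#' @param input a [calibration_input()] whose scores are normalized
#'   uncertainties.
#' @return UCE in \[0, 1\].
#' @export
uce <- function(input) {
  tb <- .bin_table(input)
  occ <- tb$count > 0
  sum(tb$count[occ] / input$n *
        abs((1 - tb$accuracy[occ]) - tb$mean_score[occ]))
}

#' Reliability curve
#'
#' The per-bin table the ECE summarizes: bin center, mean confidence,
#' accuracy and count for every occupied bin.
#'
#' @param input a [calibration_input()].
#' @return data.frame with columns bin, center, count, mean_score, accuracy.
#' @export
reliability_curve <- function(input) {
  tb <- .bin_table(input)
  tb[tb$count > 0, , drop = FALSE]
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes (one-vs-rest per class).
#'
#' @param probabilities predicted probabilities in \[0, 1\].
#' @param outcomes binary outcomes of equal length.
#' @return Brier score in \[0, 1\].
#' @export
brier <- function(probabilities, outcomes) {
  if (length(probabilities) != length(outcomes) ||
      length(probabilities) == 0L) {
    stop_validation("inputs must be equal-length and nonempty",
                    field = "probabilities")
  }
  if (any(probabilities < -1e-9 | probabilities > 1 + 1e-9)) {
    stop_validation("'probabilities' must lie in [0, 1]",
                    field = "probabilities")
  }
  mean((probabilities - as.numeric(outcomes != 0))^2)
}

#' Mean negative log-likelihood of the true class
#'
#' `-mean(log(p_true))` in nats, with probabilities floored at 1e-7.
#'
#' @param true_class_probs probability assigned to the true class, one per
#'   prediction.
#' @return NLL >= 0.
#' @export
nll <- function(true_class_probs) {
  if (length(true_class_probs) == 0L) {
    stop_validation("empty input", field = "true_class_probs")
  }
  -mean(log(pmax(true_class_probs, 1e-7)))
}

#' Uncertainty-as-error-detector ROC
#'
#' Threshold-swept ROC treating the uncertainty score as a detector of
#' incorrect predictions (incorrect = positive); AUROC by the trapezoid
#' rule.
#'
#' @param uncertainty per-prediction uncertainty score.
#' @param correct binary correctness indicator.
#' @return list with `roc` (data.frame threshold, fpr, tpr) and `auroc`.
#' @export
error_detection_roc <- function(uncertainty, correct) {
  if (length(uncertainty) != length(correct)) {
    stop_validation("length mismatch", field = "uncertainty")
  }
  err <- as.numeric(correct == 0)
  if (all(err == 0) || all(err == 1)) {
    stop_validation("AUROC undefined: correctness has a single class",
                    field = "correct")
  }
  o <- order(uncertainty, decreasing = TRUE)
  e <- err[o]
  u <- uncertainty[o]
  tp <- cumsum(e)
  fp <- cumsum(1 - e)
  keep <- c(u[-1] != u[-length(u)], TRUE)
  tpr <- c(0, tp[keep] / sum(e))
  fpr <- c(0, fp[keep] / sum(1 - e))
  auroc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(threshold = c(Inf, u[keep]), fpr = fpr, tpr = tpr),
       auroc = auroc)
}

#' Risk-coverage curve
#'
#' Predictions sorted by decreasing confidence; at coverage c the risk is
#' the error rate among the most-confident fraction c. Risk at coverage 1
#' equals the overall error rate exactly.
#'
#' @param confidence per-prediction confidence.
#' @param correct binary correctness indicator.
#' @return data.frame with columns coverage, risk.
#' @export
risk_coverage_curve <- function(confidence, correct) {
  n <- length(confidence)
  if (n == 0L || n != length(correct)) {
    stop_validation("inputs must be equal-length and nonempty",
                    field = "confidence")
  }
  o <- order(confidence, decreasing = TRUE)
  err <- as.numeric(correct[o] == 0)
  data.frame(coverage = seq_len(n) / n, risk = cumsum(err) / seq_len(n))
}

#' Paired Wilcoxon signed-rank comparison with Bonferroni correction
#'
#' Two-sided signed-rank test on paired per-case scores (exact null for
#' <= 25 nonzero pairs without ties, normal approximation otherwise; zero
#' differences dropped), with `p_adjusted = min(1, p * n_comparisons)`.
#'
#' @param model_a_scores,model_b_scores paired per-case scores.
#' @param n_comparisons number of simultaneous comparisons for the
#'   Bonferroni correction.
#' @return list with `statistic`, `p_value`, `p_adjusted`.
#' @export
paired_wilcoxon <- function(model_a_scores, model_b_scores,
                            n_comparisons = 1L) {
  if (length(model_a_scores) != length(model_b_scores)) {
    stop_validation("score vectors must be paired (equal length)",
                    field = "model_b_scores")
  }
  d <- model_b_scores - model_a_scores
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    stop_validation("degenerate test: all paired differences are zero",
                    field = "model_b_scores")
  }
  if (length(d) < 6L) {
    stop_validation("need at least 6 pairs", field = "model_a_scores")
  }
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(model_b_scores, model_a_scores, paired = TRUE,
                       exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_adjusted = min(1, wt$p.value * n_comparisons))
}

#' Segmentation robustness to bias-field perturbation
#'
#' Per-class mean Dice drop `mean DSC(unperturbed) - mean DSC(perturbed)`
#' when every case's volume is corrupted by a seeded multiplicative bias
#' field of the given amplitude before inference.
#'
#' @param net a stochastic `glioseg_network` (or fused model).
#' @param cases list of cases, each a list with `volume` and `labels`.
#' @param bias_amplitude non-negative perturbation amplitude.
#' @param T_samples stochastic passes per prediction.
#' @param seed integer seed (drives both the fields and the passes).
#' @param relabel optional [relabel_config()] applied to both arms.
#' @return list with `delta_dsc` (named per-class vector), and the two
#'   per-case DSC tables `dsc_clean`, `dsc_perturbed`.
#' @export
delta_dsc_robustness <- function(net, cases, bias_amplitude, T_samples = 10L,
                                 seed = 1L, relabel = NULL) {
  check_scalar_num(bias_amplitude, "bias_amplitude", min = 0)
  cls <- 1:3
  n <- length(cases)
  dsc_clean <- dsc_pert <- matrix(NA_real_, nrow = n, ncol = 3,
                                  dimnames = list(NULL, c("FHR", "ER", "NENR")))
  for (i in seq_len(n)) {
    ca <- cases[[i]]
    pr <- predict_case(net, ca$volume, T_samples = T_samples,
                       relabel = relabel, seed = seed + i)
    vol_p <- apply_bias_field(ca$volume, bias_amplitude, seed = seed + 1000L + i)
    pr2 <- predict_case(net, vol_p, T_samples = T_samples,
                        relabel = relabel, seed = seed + i)
    for (k in cls) {
      dsc_clean[i, k] <- dice(pr$labels, ca$labels, k)
      dsc_pert[i, k] <- dice(pr2$labels, ca$labels, k)
    }
  }
  list(delta_dsc = colMeans(dsc_clean) - colMeans(dsc_pert),
       dsc_clean = dsc_clean, dsc_perturbed = dsc_pert)
}
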