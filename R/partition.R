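#' Absolute expression difference (AED)
#'
#' AED is the absolute value of the log2 fold change between mean stressed
#' and mean control expression, with a pseudocount guarding zero FPKM:
#' `|log2((mean_stress + eps) / (mean_ctrl + eps))|`.
#'
#' @param mean_ctrl,mean_stress Mean FPKM per condition (vectors).
#' @param eps Pseudocount added to both means; default 0.01 FPKM.
#' @return Non-negative AED values in log2 units.
#' @export
#' @examples
#' compute_aed(1, 4, eps = 0)   # 2
compute_aed <- function(mean_ctrl, mean_stress, eps = 0.01) {
  abs(log2((mean_stress + eps) / (mean_ctrl + eps)))
}

#' Peak of the ecdf-difference curve between two AED samples
#'
#' Evaluates `D(t) = F_down(t) - F_up(t)` at every pooled sorted sample
#' value (the only points where either step function changes) and returns
#' the smallest t attaining the maximum.  Used to place the weak/strong
#' boundary for [assign_subgroups()].
#'
#' @param aed_up,aed_down AED samples for up- and downregulated genes.
#' @return A list with `t_star` (peak location), `max_d` (peak height), and
#'   `curve` (data.frame of `t`, `d`).
#' @export
ecdf_difference_peak <- function(aed_up, aed_down) {
  if (length(aed_up) == 0 || length(aed_down) == 0)
    stop("both samples must be non-empty")
  t <- sort(unique(c(aed_up, aed_down)))
  d <- ecdf(aed_down)(t) - ecdf(aed_up)(t)
  ## smallest argmax; the tolerance absorbs floating-point noise in exact
  ## ties (true differences are at least 1 / (n_up * n_down) >> 1e-9)
  i <- which(d >= max(d) - 1e-9)[1]
  list(t_star = t[i], max_d = d[i], curve = data.frame(t = t, d = d))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup_t |F_x(t) - F_y(t)|` evaluated over the pooled sample points.
#' The p-value comes from the asymptotic Kolmogorov distribution at
#' effective size `n = n_x n_y / (n_x + n_y)`; with `exact = TRUE` (allowed
#' for `n_x + n_y <= 16`) it is instead computed by enumerating all
#' re-assignments of the pooled values to the two groups.
#'
#' @param x,y Numeric samples.
#' @param exact Logical; exact-by-enumeration p-value for small samples.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  Dstat <- function(a, b) {
    t <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(t) - ecdf(b)(t)))
  }
  D <- Dstat(x, y)
  nx <- length(x); ny <- length(y)
  if (exact) {
    if (nx + ny > 16)
      stop("exact enumeration supported only for n_x + n_y <= 16")
    pooled <- c(x, y)
    combos <- utils::combn(nx + ny, nx)
    ds <- apply(combos, 2, function(idx)
      Dstat(pooled[idx], pooled[-idx]))
    p <- mean(ds >= D - 1e-12)
  } else {
    n_eff <- nx * ny / (nx + ny)
    lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * lambda^2 * k^2))
    p <- min(1, max(0, p))
  }
  list(statistic = D, p_value = p)
}

#' Assign strong/weak subgroups at an AED threshold
#'
#' Significant genes with AED above the threshold are strongly regulated,
#' those at or below it weakly regulated, each in the direction of their
#' fold change; non-significant genes are `unchanged`.  Percentages are
#' reported within direction and rounded half-up to integers.
#'
#' @param records Data.frame with columns `aed`, `direction` (`"up"`,
#'   `"down"`, `"none"`) and `significant` (logical); see
#'   [partition_expression()] for building it from FPKM.
#' @param t_star Positive AED threshold (log2 units).
#' @return List with `records` (input plus `subgroup`), `counts` (named
#'   integer vector over the four subgroups), and `percentages` (integer
#'   percentages within direction; empty when a direction has no genes).
#' @export
assign_subgroups <- function(records, t_star) {
  stopifnot(is.data.frame(records), t_star > 0,
            all(c("aed", "direction", "significant") %in% names(records)))
  sub <- rep("unchanged", nrow(records))
  sig <- records$significant & records$direction %in% c("up", "down")
  strength <- ifelse(records$aed > t_star, "strong", "weak")
  sub[sig] <- paste0(strength[sig], "_", records$direction[sig])
  records$subgroup <- sub
  lv <- c("strong_up", "weak_up", "strong_down", "weak_down")
  counts <- vapply(lv, function(g) sum(sub == g), integer(1))
  pct <- integer(0)
  for (dir in c("up", "down")) {
    tot <- counts[paste0("strong_", dir)] + counts[paste0("weak_", dir)]
    if (tot > 0) {
      for (st in c("strong", "weak")) {
        nm <- paste0(st, "_", dir)
        pct[nm] <- floor(100 * counts[nm] / tot + 0.5)  # round half-up
      }
    }
  }
  list(records = records, counts = counts, percentages = pct)
}

#' Partition differentially expressed genes by AED
#'
#' End-to-end partition: computes per-condition mean FPKM, log2 fold change
#' and AED, locates the weak/strong boundary at the peak of the
#' downregulated-minus-upregulated ecdf-difference curve, labels the four
#' subgroups, and compares the two AED distributions with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param expr Data.frame with `gene_id`, FPKM columns matching
#'   `fpkm_ctrl_*` and `fpkm_stress_*`, and logical `significant`.
#' @param eps FPKM pseudocount for fold-change computation.
#' @return List with `records` (per-gene table incl. `log2fc`, `aed`,
#'   `direction`, `subgroup`), `t_star`, `curve`, `counts`, `percentages`,
#'   `ks` (KS test of up vs down AED), and `qq` (quantile-pair table for a
#'   Q-Q plot, type-7 quantiles).
#' @export
partition_expression <- function(expr, eps = 0.01) {
  stopifnot(is.data.frame(expr), "significant" %in% names(expr))
  ctrl_cols <- grep("^fpkm_ctrl", names(expr), value = TRUE)
  str_cols <- grep("^fpkm_stress", names(expr), value = TRUE)
  if (length(ctrl_cols) == 0 || length(str_cols) == 0)
    stop("expected fpkm_ctrl_* and fpkm_stress_* columns")
  mean_ctrl <- rowMeans(expr[, ctrl_cols, drop = FALSE])
  mean_stress <- rowMeans(expr[, str_cols, drop = FALSE])
  log2fc <- log2((mean_stress + eps) / (mean_ctrl + eps))
  rec <- data.frame(gene_id = expr$gene_id,
                    mean_ctrl = mean_ctrl, mean_stress = mean_stress,
                    log2fc = log2fc, aed = abs(log2fc),
                    significant = expr$significant,
                    stringsAsFactors = FALSE)
  rec$direction <- ifelse(!rec$significant, "none",
                          ifelse(rec$log2fc >= 0, "up", "down"))
  aed_up <- rec$aed[rec$direction == "up"]
  aed_down <- rec$aed[rec$direction == "down"]
  peak <- ecdf_difference_peak(aed_up, aed_down)
  part <- assign_subgroups(rec, peak$t_star)
  p <- seq(0.01, 0.99, by = 0.01)
  qq <- data.frame(p = p,
                   q_up = quantile(aed_up, p, type = 7, names = FALSE),
                   q_down = quantile(aed_down, p, type = 7, names = FALSE))
  list(records = part$records, t_star = peak$t_star, max_d = peak$max_d,
       curve = peak$curve, counts = part$counts,
       percentages = part$percentages,
       ks = ks_two_sample(aed_up, aed_down), qq = qq)
}
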