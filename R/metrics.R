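#' Benchmark table of predicted vs experimental ddG
#'
#' Validates and classes a per-pair benchmark table with columns `pair_id`,
#' `target_name`, `ddg_cal`, `ddg_exp` (kcal/mol) and optionally `overlap`.
#'
#' @param df a data frame.
#' @return the table with class `benchmark_table`.
#' @export
benchmark_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("pair_id", "ddg_cal", "ddg_exp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    neqfe_stop(paste("benchmark table missing columns:",
                     paste(miss, collapse = ", ")))
  if (!"target_name" %in% names(df)) df$target_name <- "all"
  if (anyDuplicated(df$pair_id)) neqfe_stop("pair_id values must be unique")
  if (any(!is.finite(df$ddg_cal)) || any(!is.finite(df$ddg_exp)))
    neqfe_stop("ddG values must be finite")
  class(df) <- c("benchmark_table", "data.frame")
  df
}

metrics_of <- function(cal, exp_) {
  e <- cal - exp_
  r <- if (sd(cal) > 0 && sd(exp_) > 0 && length(e) >= 2) cor(cal, exp_)
       else NA_real_
  c(mue = mean(abs(e)), mse = mean(e), rmse = sqrt(mean(e^2)), r = r)
}

#' Prediction-vs-experiment error metrics with bootstrap errors
#'
#' Computes the mean unsigned error (MUE), mean signed error (MSE),
#' root-mean-square error (RMSE) and the Pearson correlation coefficient r
#' between calculated and experimental ddG, each with a bootstrap standard
#' error obtained by resampling rows (ligand pairs) with replacement. When
#' either column has zero variance, r is undefined and reported as `NA`;
#' the error metrics are still returned.
#'
#' @param table a [benchmark_table] with >= 2 rows.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return a data frame with columns `metric`, `value`, `se`.
#' @examples
#' tab <- benchmark_table(data.frame(pair_id = 1:3,
#'   ddg_cal = c(1, -0.5, 2), ddg_exp = c(0.5, 0, 1)))
#' error_metrics(tab, n_boot = 100, seed = 1)
#' @export
error_metrics <- function(table, n_boot = 1000L, seed = NULL) {
  table <- benchmark_table(table)
  if (nrow(table) < 2) neqfe_stop("error metrics require >= 2 pairs")
  v <- metrics_of(table$ddg_cal, table$ddg_exp)
  se <- with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(table), replace = TRUE)
      metrics_of(table$ddg_cal[idx], table$ddg_exp[idx])
    }, numeric(4))
    apply(boots, 1, function(x) if (anyNA(x)) NA_real_ else sd(x))
  })
  data.frame(metric = names(v), value = unname(v), se = unname(se))
}

#' Per-target benchmark metrics plus the pooled summary
#'
#' Computes [error_metrics()] separately for every protein target and once
#' for the full table (target `"all"`, which equals `error_metrics` on the
#' pooled data). Targets with fewer than 2 pairs are excluded with a
#' warning.
#'
#' @inheritParams error_metrics
#' @return a long data frame with columns `target`, `n_pairs`, `metric`,
#'   `value`, `se`.
#' @export
per_target_summary <- function(table, n_boot = 1000L, seed = NULL) {
  table <- benchmark_table(table)
  targets <- unique(table$target_name)
  rows <- lapply(targets, function(tg) {
    sub <- table[table$target_name == tg, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning(sprintf("target %s has %d pair(s); excluded from the summary",
                      tg, nrow(sub)))
      return(NULL)
    }
    m <- error_metrics(sub, n_boot = n_boot, seed = seed)
    cbind(data.frame(target = tg, n_pairs = nrow(sub)), m)
  })
  pooled <- cbind(data.frame(target = "all", n_pairs = nrow(table)),
                  error_metrics(table, n_boot = n_boot, seed = seed))
  rbind(do.call(rbind, rows), pooled)
}

#' Paired bootstrap comparison of two methods' error metrics
#'
#' Tests whether two prediction methods evaluated on the same ligand pairs
#' differ in MUE/MSE/RMSE: resamples pairs with replacement, computes the
#' metric difference (method A - method B) in each resample, and reports
#' the two-sided 95% percentile interval. The difference is flagged
#' significant when the interval excludes zero.
#'
#' @param table_a,table_b [benchmark_table]s sharing `pair_id` values and
#'   `ddg_exp`.
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @return a data frame with columns `metric`, `difference`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
paired_metric_test <- function(table_a, table_b, n_boot = 10000L, seed = 1L) {
  table_a <- benchmark_table(table_a)
  table_b <- benchmark_table(table_b)
  common <- intersect(table_a$pair_id, table_b$pair_id)
  if (length(common) < 2) neqfe_stop("fewer than 2 shared pairs")
  a <- table_a[match(common, table_a$pair_id), ]
  b <- table_b[match(common, table_b$pair_id), ]
  stat <- function(idx) {
    metrics_of(a$ddg_cal[idx], a$ddg_exp[idx])[1:3] -
      metrics_of(b$ddg_cal[idx], b$ddg_exp[idx])[1:3]
  }
  d0 <- stat(seq_along(common))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    stat(sample.int(length(common), replace = TRUE)), numeric(3)))
  ci <- apply(boots, 1, quantile, probs = c(0.025, 0.975))
  data.frame(metric = names(d0), difference = unname(d0),
             ci_low = unname(ci[1, ]), ci_high = unname(ci[2, ]),
             significant = unname(ci[1, ] > 0 | ci[2, ] < 0))
}
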