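# kJ/mol per kcal/mol
KJ_PER_KCAL <- 4.184

detect_sep <- function(path) {
  l1 <- readLines(path, n = 25L)
  l1 <- l1[!startsWith(l1, "#")]
  if (length(l1) == 0) neqfe_stop(sprintf("%s: no content", path))
  if (grepl("\t", l1[1])) "\t" else ","
}

read_delim_checked <- function(path, required, sep = NULL) {
  if (!file.exists(path)) neqfe_stop(sprintf("file not found: %s", path))
  if (is.null(sep)) sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, blank.lines.skip = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    neqfe_stop(sprintf("%s: missing columns: %s", path,
                       paste(miss, collapse = ", ")))
  df
}

check_enum <- function(df, column, allowed, path) {
  bad <- which(!(df[[column]] %in% allowed))
  if (length(bad) > 0)
    neqfe_stop(sprintf(
      "%s: invalid %s value(s) %s at data row(s) %s (allowed: %s)",
      path, column, paste(unique(df[[column]][bad]), collapse = ", "),
      paste(head(bad, 10), collapse = ", "), paste(allowed, collapse = ", ")))
}

check_numeric <- function(df, column, path) {
  v <- suppressWarnings(as.numeric(df[[column]]))
  bad <- which(is.na(v))
  if (length(bad) > 0)
    neqfe_stop(sprintf("%s: non-numeric %s at data row(s) %s", path, column,
                       paste(head(bad, 10), collapse = ", ")))
  v
}

#' Read a work table into work sets
#'
#' Parses a delimited (comma or tab) text file with header columns
#' `pair_id`, `leg`, `direction`, `replica_id`, `snapshot_time_ps`,
#' `work_kcal_mol`, `completed` (0/1) and optional `temperature_K`
#' (constant per pair x leg group, default 300), one row per switching
#' transition, and groups the rows into [work_set] objects by pair and leg.
#' Malformed rows are rejected with their row numbers. Lines starting with
#' `#` are treated as comments.
#'
#' @param path file path.
#' @param units `"kcal"` (native) or `"kj"` (converted on read, / 4.184).
#' @return a named list of [work_set] objects (`pair_id.leg`).
#' @export
read_work_table <- function(path, units = c("kcal", "kj")) {
  units <- match.arg(units)
  req <- c("pair_id", "leg", "direction", "replica_id", "snapshot_time_ps",
           "work_kcal_mol", "completed")
  df <- read_delim_checked(path, req)
  check_enum(df, "leg", c("complex", "solvent"), path)
  check_enum(df, "direction", c("forward", "reverse"), path)
  check_enum(df, "completed", c(0, 1, "0", "1"), path)
  df$work_kcal_mol <- check_numeric(df, "work_kcal_mol", path)
  df$snapshot_time_ps <- check_numeric(df, "snapshot_time_ps", path)
  if (units == "kj") df$work_kcal_mol <- df$work_kcal_mol / KJ_PER_KCAL
  if (!"temperature_K" %in% names(df)) df$temperature_K <- 300
  groups <- split(df, list(df$pair_id, df$leg), drop = TRUE)
  out <- lapply(groups, function(g) {
    temps <- unique(g$temperature_K)
    if (length(temps) > 1)
      neqfe_stop(sprintf("%s: mixed temperatures within pair %s (%s leg)",
                         path, g$pair_id[1], g$leg[1]))
    mk <- function(d) data.frame(replica_id = as.integer(d$replica_id),
                                 snapshot_time_ps = d$snapshot_time_ps,
                                 completed = d$completed %in% c(1, "1"))
    f <- g[g$direction == "forward", , drop = FALSE]
    r <- g[g$direction == "reverse", , drop = FALSE]
    work_set(f$work_kcal_mol, r$work_kcal_mol, pair_id = g$pair_id[1],
             leg = g$leg[1], temperature = temps,
             forward_meta = mk(f), reverse_meta = mk(r))
  })
  out
}

provenance_header <- function(seed = NULL, config_hash = NULL) {
  h <- character()
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  if (!is.null(config_hash)) h <- c(h, sprintf("# config_hash: %s", config_hash))
  h
}

write_with_header <- function(df, path, sep, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0) writeLines(header_lines, con)
  write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Write work sets to a delimited work table
#'
#' Inverse of [read_work_table()]: numeric values are written with 17
#' significant digits so a read round-trip is lossless. Optional seed /
#' configuration-hash provenance is embedded as `#` comment lines.
#'
#' @param work_sets a [work_set] or list of them.
#' @param path output file path.
#' @param sep `","` or `"\t"`.
#' @param seed,config_hash optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_work_table <- function(work_sets, path, sep = ",", seed = NULL,
                             config_hash = NULL) {
  if (inherits(work_sets, "work_set")) work_sets <- list(work_sets)
  rows <- lapply(work_sets, function(ws) {
    one <- function(direction) {
      d <- ws[[direction]]
      if (nrow(d) == 0) return(NULL)
      data.frame(pair_id = ws$pair_id, leg = ws$leg, direction = direction,
                 replica_id = d$replica_id,
                 snapshot_time_ps = fmt_num(d$snapshot_time_ps),
                 work_kcal_mol = fmt_num(d$work),
                 completed = as.integer(d$completed),
                 temperature_K = fmt_num(ws$temperature))
    }
    rbind(one("forward"), one("reverse"))
  })
  write_with_header(do.call(rbind, rows), path, sep,
                    provenance_header(seed, config_hash))
  invisible(path)
}

#' Read a dH/dlambda table
#'
#' Columns: `pair_id`, `leg`, `replica_id`, `lambda`, `dhdl_kcal_mol`.
#'
#' @inheritParams read_work_table
#' @return a [dhdl_table].
#' @export
read_dhdl_table <- function(path, units = c("kcal", "kj")) {
  units <- match.arg(units)
  df <- read_delim_checked(path, c("pair_id", "leg", "replica_id", "lambda",
                                   "dhdl_kcal_mol"))
  check_enum(df, "leg", c("complex", "solvent"), path)
  df$lambda <- check_numeric(df, "lambda", path)
  df$dhdl <- check_numeric(df, "dhdl_kcal_mol", path)
  if (units == "kj") df$dhdl <- df$dhdl / KJ_PER_KCAL
  dhdl_table(df[c("pair_id", "leg", "replica_id", "lambda", "dhdl")])
}

#' Write a dH/dlambda table
#'
#' @param table a [dhdl_table].
#' @inheritParams write_work_table
#' @return `path`, invisibly.
#' @export
write_dhdl_table <- function(table, path, sep = ",", seed = NULL,
                             config_hash = NULL) {
  if (!inherits(table, "dhdl_table")) table <- dhdl_table(table)
  out <- data.frame(pair_id = table$pair_id, leg = table$leg,
                    replica_id = table$replica_id,
                    lambda = fmt_num(table$lambda),
                    dhdl_kcal_mol = fmt_num(table$dhdl))
  write_with_header(out, path, sep, provenance_header(seed, config_hash))
  invisible(path)
}

#' Read a benchmark table
#'
#' Columns: `pair_id`, `target_name`, `ddg_cal_kcal_mol`,
#' `ddg_exp_kcal_mol`, optional `overlap`.
#'
#' @inheritParams read_work_table
#' @return a [benchmark_table].
#' @export
read_benchmark_table <- function(path, units = c("kcal", "kj")) {
  units <- match.arg(units)
  df <- read_delim_checked(path, c("pair_id", "ddg_cal_kcal_mol",
                                   "ddg_exp_kcal_mol"))
  df$ddg_cal <- check_numeric(df, "ddg_cal_kcal_mol", path)
  df$ddg_exp <- check_numeric(df, "ddg_exp_kcal_mol", path)
  if (units == "kj") {
    df$ddg_cal <- df$ddg_cal / KJ_PER_KCAL
    df$ddg_exp <- df$ddg_exp / KJ_PER_KCAL
  }
  keep <- intersect(c("pair_id", "target_name", "ddg_cal", "ddg_exp",
                      "overlap"), names(df))
  benchmark_table(df[keep])
}

#' Write a benchmark table
#'
#' @param table a [benchmark_table].
#' @inheritParams write_work_table
#' @return `path`, invisibly.
#' @export
write_benchmark_table <- function(table, path, sep = ",", seed = NULL,
                                  config_hash = NULL) {
  table <- benchmark_table(table)
  out <- data.frame(pair_id = table$pair_id, target_name = table$target_name,
                    ddg_cal_kcal_mol = fmt_num(table$ddg_cal),
                    ddg_exp_kcal_mol = fmt_num(table$ddg_exp))
  if ("overlap" %in% names(table)) out$overlap <- fmt_num(table$overlap)
  write_with_header(out, path, sep, provenance_header(seed, config_hash))
  invisible(path)
}

#' Combine the two legs of the thermodynamic cycle
#'
#' ddG = dG_complex - dG_solvent, with the uncertainties added in
#' quadrature. This closes the relative-binding thermodynamic cycle: the
#' alchemical transformation is carried out once with the ligand bound
#' (complex leg) and once in bulk solvent.
#'
#' @param complex,solvent [fe_estimate]s for the two legs.
#' @return a list with `ddg`, `uncertainty`, `estimator`.
#' @examples
#' combine_legs(fe_estimate(1.0, 0.3, "bar"), fe_estimate(0.2, 0.4, "bar"))
#' @export
combine_legs <- function(complex, solvent) {
  stopifnot(inherits(complex, "fe_estimate"), inherits(solvent, "fe_estimate"))
  u <- if (is.na(complex$uncertainty) || is.na(solvent$uncertainty)) NA_real_
       else sqrt(complex$uncertainty^2 + solvent$uncertainty^2)
  list(ddg = complex$dg - solvent$dg, uncertainty = u,
       estimator = complex$estimator)
}

RUN_CONFIG_KEYS <- list(
  seed = NULL, output_dir = NULL, estimator = NULL,
  crooks = c("true_dg", "sigma_f", "sigma_r", "n_forward", "n_reverse",
             "temperature", "shape", "mixture_params", "seed", "n_replicas",
             "run_length_ps", "failure_rate"),
  dhdl = c("profile_coefficients", "n_windows", "n_replicas",
           "samples_per_window", "noise_sd", "seed"),
  benchmark = c("n_pairs", "ddg_range", "experimental_noise_sd", "seed",
                "n_targets"),
  protocol = c("n_replicas", "eq_duration_ns", "n_transitions",
               "transition_length_ps", "delta_lambda", "total_duration_ps"))

#' Read and validate a pipeline run configuration
#'
#' Flat YAML with top-level sections `crooks`, `dhdl`, `benchmark`,
#' `protocol` and scalar keys `seed`, `output_dir`, `estimator`. Unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return the validated configuration list, with a `config_hash` attribute.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) neqfe_stop(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(RUN_CONFIG_KEYS))
  if (length(unknown) > 0)
    neqfe_stop(sprintf("unknown config key(s): %s",
                       paste(unknown, collapse = ", ")))
  for (sec in c("crooks", "dhdl", "benchmark", "protocol")) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), RUN_CONFIG_KEYS[[sec]])
      if (length(bad) > 0)
        neqfe_stop(sprintf("unknown key(s) in section %s: %s", sec,
                           paste(bad, collapse = ", ")))
    }
  }
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

# order-insensitive content hash of a config list (djb2 over the
# deparsed canonical form; provenance marker, not cryptographic)
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) x <- lapply(x[order(names(x))], canon)
    x
  }
  s <- paste(deparse(canon(unclass(cfg))), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
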