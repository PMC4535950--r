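#' Derive per-replicate seeds
#'
#' Deterministic Lehmer-style hash of (master seed, condition id, replicate
#' id), kept below 2^31 so the result is always a valid [set.seed()] input.
#' No stream is shared between replicates of a sweep, and the whole sweep
#' is reproducible from the master seed alone.
#'
#' @param master_seed integer master seed.
#' @param condition_id integer id of the sweep condition (grid position).
#' @param replicates number of replicate seeds to derive.
#' @return integer vector of length `replicates`.
#' @export
replicate_seeds <- function(master_seed, condition_id, replicates) {
  M <- 2147483647
  h0 <- ((master_seed %% M) * 48271 + condition_id) %% M
  vapply(seq_len(replicates), function(k) as.integer((h0 * 48271 + k) %% M),
         integer(1))
}

study_indices_once <- function(config, engine) {
  if (engine == "cpp") {
    g <- default_extreme_groups(config$scale_max)
    cpp_study_indices(config$n_items, config$n_experts, config$gci,
                      config$scale_max, config$clustering$cluster_width,
                      config$clustering$secondary_threshold, config$n_rounds,
                      g$lower, g$upper)
  } else {
    run_study(config)$study_wide
  }
}

#' Monte-Carlo replicates of one survey condition
#'
#' Runs `replicates` independent simulated studies under one configuration
#' and summarises each consensus index by the median of its study-wide
#' values (even replicate counts average the two central order statistics).
#'
#' @param config a [simulation_config()]; its `seed` field is ignored in
#'   favour of `seeds`.
#' @param replicates number of replicate studies.
#' @param seeds optional integer vector of per-replicate seeds (length
#'   `replicates`); defaults to [replicate_seeds()] from `master_seed`.
#' @param master_seed used to derive `seeds` when they are not supplied.
#' @param engine `"cpp"` (compiled core, the default) or `"r"` (reference
#'   path); both produce identical studies from identical seeds.
#' @param keep_values if `TRUE`, attach the full replicates-by-index matrix
#'   of study-wide values as attribute `"values"`.
#' @return named numeric vector of nine per-index medians.
#' @export
run_condition <- function(config, replicates, seeds = NULL, master_seed = 1L,
                          engine = c("cpp", "r"), keep_values = FALSE) {
  engine <- match.arg(engine)
  if (is.null(seeds)) seeds <- replicate_seeds(master_seed, 0L, replicates)
  if (length(seeds) != replicates)
    stop("`seeds` must have one entry per replicate", call. = FALSE)
  config$seed <- NULL
  vals <- matrix(NA_real_, nrow = replicates, ncol = 9L,
                 dimnames = list(NULL, INDEX_NAMES))
  for (k in seq_len(replicates)) {
    set.seed(seeds[[k]])
    vals[k, ] <- study_indices_once(config, engine)
  }
  med <- apply(vals, 2L, median)
  if (keep_values) attr(med, "values") <- vals
  med
}

#' Specification of a one-parameter dependency sweep
#'
#' Varies exactly one survey characteristic over a grid while the other two
#' stay at the baseline (12 questions, 20 experts, GCI 0.5).  Default
#' grids span the ranges studied: questions 6..40, experts 6..50, GCI 0 to
#' 1 in steps of 0.1.
#'
#' @param param which characteristic to vary: `"n_items"`, `"n_experts"` or
#'   `"gci"` (aliases `"items"`, `"questions"`, `"experts"` accepted).
#' @param grid ordered values to sweep; `NULL` for the default grid.
#' @param baseline a [simulation_config()] holding the fixed parameters.
#' @param replicates Monte-Carlo replicates per grid point (default 1000).
#' @param master_seed master seed from which all replicate seeds derive.
#' @return a list of class `"sweep_spec"`.
#' @export
sweep_spec <- function(param = c("n_items", "n_experts", "gci"), grid = NULL,
                       baseline = simulation_config(), replicates = 1000L,
                       master_seed = 1L) {
  aliases <- c(items = "n_items", questions = "n_items", experts = "n_experts",
               n_items = "n_items", n_experts = "n_experts", gci = "gci")
  param <- as.character(param)[1L]
  if (!param %in% names(aliases))
    stop("`param` must be one of n_items, n_experts, gci", call. = FALSE)
  param <- aliases[[param]]
  if (is.null(grid))
    grid <- switch(param,
                   n_items = 6:40,
                   n_experts = 6:50,
                   gci = seq(0, 1, by = 0.1))
  if (length(grid) < 1L) stop("`grid` must be non-empty", call. = FALSE)
  if (param %in% c("n_items", "n_experts") && any(grid != round(grid)))
    stop("`grid` for a count parameter must be integer-valued", call. = FALSE)
  if (param == "gci" && any(grid < 0 | grid > 1))
    stop("`gci` grid must lie in [0, 1]", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  structure(list(param = param, grid = grid, baseline = baseline,
                 replicates = replicates,
                 master_seed = as.integer(master_seed)),
            class = "sweep_spec")
}

#' Run a dependency sweep
#'
#' For every grid point, runs [run_condition()] with the swept parameter
#' substituted into the baseline, then computes each index's
#' \emph{dependency}: the maximum minus the minimum of its per-condition
#' medians.  The IQR dependency is normalised by the scale length
#' (`scale_max - 1`, i.e. 9 on a 1-10 scale) so all nine dependencies share
#' the 0-1 range; the other indices already live there.
#'
#' @param spec a [sweep_spec()].
#' @param engine `"cpp"` or `"r"`, see [run_condition()].
#' @return a `data.frame` of class `"dependency_table"` with columns
#'   `index`, `dependency`, `rank` (indices ordered by descending
#'   dependency), and attributes `medians` (conditions x indices matrix),
#'   `grid`, `param`, `raw_dependency` (pre-normalisation values) and
#'   `replicates`.
#' @examples
#' \donttest{
#' spec <- sweep_spec("gci", grid = c(0, 0.5, 1), replicates = 50)
#' run_sweep(spec)
#' }
#' @export
run_sweep <- function(spec, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  medians <- matrix(NA_real_, nrow = length(spec$grid), ncol = 9L,
                    dimnames = list(NULL, INDEX_NAMES))
  for (ci in seq_along(spec$grid)) {
    cfg <- spec$baseline
    cfg[[spec$param]] <- if (spec$param == "gci") spec$grid[[ci]]
                         else as.integer(spec$grid[[ci]])
    # condition id from the swept value, not the grid position, so
    # reordering the grid reorders but never changes the medians
    cid <- as.integer(round(spec$grid[[ci]] * 1000))
    seeds <- replicate_seeds(spec$master_seed, cid, spec$replicates)
    medians[ci, ] <- run_condition(cfg, spec$replicates, seeds = seeds,
                                   engine = engine)
  }
  raw <- apply(medians, 2L, max) - apply(medians, 2L, min)
  dep <- raw
  dep[["IQR"]] <- raw[["IQR"]] / (spec$baseline$scale_max - 1)
  ord <- order(-dep)
  tab <- data.frame(index = INDEX_NAMES[ord],
                    dependency = unname(dep[ord]),
                    rank = seq_along(dep))
  structure(tab,
            class = c("dependency_table", "data.frame"),
            medians = medians, grid = spec$grid, param = spec$param,
            raw_dependency = raw, replicates = spec$replicates)
}

#' @export
print.dependency_table <- function(x, ...) {
  cat(sprintf("Dependency of consensus indices on %s (%d conditions, %d replicates each)\n",
              attr(x, "param"), length(attr(x, "grid")), attr(x, "replicates")))
  df <- as.data.frame(x)
  df$dependency <- sprintf("%.3f", df$dependency)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Dependency of a single index
#'
#' @param tab a `"dependency_table"`.
#' @param index index abbreviation (DM, PWA, CPWA, XCPWA, KF, KC, M, CM,
#'   IQR).
#' @return the (normalised) dependency value.
#' @export
dependency_of <- function(tab, index) {
  index <- match.arg(index, INDEX_NAMES)
  tab$dependency[match(index, tab$index)]
}

#' Reproduce the three dependency tables
#'
#' Runs the three canonical one-at-a-time sweeps — number of questions
#' (6..40), number of experts (6..50) and Group Conformity Index (0..1) —
#' each against the 12-question / 20-expert / GCI-0.5 baseline, and returns
#' the three rank-ordered dependency tables.
#'
#' @param master_seed master seed for all three sweeps.
#' @param replicates Monte-Carlo replicates per condition (default 1000).
#' @param baseline a [simulation_config()].
#' @param engine `"cpp"` or `"r"`.
#' @return a named list of three `"dependency_table"`s: `questions`,
#'   `experts`, `gci`.
#' @export
dependency_tables <- function(master_seed = 1L, replicates = 1000L,
                              baseline = simulation_config(),
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  run1 <- function(param, offset)
    run_sweep(sweep_spec(param, baseline = baseline, replicates = replicates,
                         master_seed = master_seed + offset),
              engine = engine)
  list(questions = run1("n_items", 0L),
       experts = run1("n_experts", 1L),
       gci = run1("gci", 2L))
}
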