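#' @name experiments
#' @title Simulation drivers: randomization trajectories and corner/middle censuses
#'
#' @description
#' These drivers reproduce the package's central simulations. Starting from
#' the identity permutation, k genomes are progressively scrambled by
#' random gene-position swaps; at each randomization level the breakpoint
#' median is solved exactly and m alternative optima are sampled by varying
#' the solver's tie-breaking seed. Tracked statistics: the normalized
#' median sum (which saturates at the asymptote k - 1), the mean pairwise
#' normalized distance between alternative solutions (approaching
#' (k - 1)/k from below), and the census of solutions classified as
#' corner (near one input) versus middle (approximately equidistant from
#' all inputs).
#'
#' All randomness flows from one master seed. Sub-seeds are drawn up front
#' with `sample.int(2146483646)` in record order -- for each randomization
#' level, then each replicate: one seed per input genome, then one solver
#' base seed -- so trajectories for different k or n share no randomness
#' and every record is replayable in isolation.
NULL

derive_seeds <- function(master, count) {
  set.seed(as.integer(master))
  sample.int(2146483646L, count)
}

trajectory_record <- function(n, k, signed, s, rep_id, m, sols, inst, tau) {
  cls <- lapply(sols, classify_median, inst = inst, tau = tau)
  corners <- vapply(cls, function(c) if (is.na(c$corner)) 0L else c$corner, integer(1))
  counts <- tabulate(corners, nbins = k)
  rec <- data.frame(n = n, k = k, signed = signed, swaps_per_100 = s,
                    replicate = rep_id,
                    normalized_median_sum = sols[[1L]]$median_sum / n,
                    mean_solution_distance = mean_pairwise_distance(sols),
                    middle_count = sum(corners == 0L),
                    mean_nearest_input_distance =
                      mean(vapply(cls, `[[`, numeric(1), "nearest_input_distance")),
                    m_solutions = m, valid = TRUE)
  for (i in seq_len(k)) rec[[paste0("corner_", i)]] <- counts[i]
  rec
}

invalid_record <- function(n, k, signed, s, rep_id, m, msg) {
  rec <- data.frame(n = n, k = k, signed = signed, swaps_per_100 = s,
                    replicate = rep_id,
                    normalized_median_sum = NA_real_,
                    mean_solution_distance = NA_real_,
                    middle_count = NA_integer_,
                    mean_nearest_input_distance = NA_real_,
                    m_solutions = m, valid = FALSE)
  for (i in seq_len(k)) rec[[paste0("corner_", i)]] <- NA_integer_
  warning("solver failure at swaps_per_100 = ", s, ", replicate ", rep_id,
          ": ", msg, call. = FALSE)
  rec
}

#' Median statistics along a randomization trajectory
#'
#' For each swap level `s` (in swaps per 100 genes) and each replicate,
#' generates `k` input genomes by applying `round(s * n / 100)` random
#' gene-position swaps to the identity genome (independent seed streams per
#' genome), samples `m_solutions` optimal medians, and records the
#' normalized median sum, the mean pairwise distance between sampled
#' solutions, and corner/middle classification counts. Solver failures
#' yield a record with `valid = FALSE`, never a silent drop.
#'
#' @param n gene count.
#' @param k number of input genomes (>= 3).
#' @param signed logical.
#' @param swap_levels numeric vector of swap counts per 100 genes; default
#'   a grid from 0 to `max_swaps_per_100` in steps of `step`.
#' @param max_swaps_per_100,step define the default grid.
#' @param reps replicates per level.
#' @param m_solutions optimal medians sampled per instance.
#' @param seed master seed.
#' @param mode solver mode, see [solve_median_tsp()]; trajectory statistics
#'   are meaningful under certified (`"exact"`) solves.
#' @param tau middle/corner spread threshold, see [classify_median()].
#' @param time_limit per-solve budget in seconds.
#' @return A `data.frame`, one row per (level, replicate): columns `n`,
#'   `k`, `signed`, `swaps_per_100`, `replicate`, `normalized_median_sum`,
#'   `mean_solution_distance`, `middle_count`,
#'   `mean_nearest_input_distance`, `m_solutions`, `valid`, and
#'   `corner_1..corner_k`. Configuration is attached as attribute
#'   `config`.
#' @examples
#' \donttest{
#' tr <- randomization_trajectory(30, seed = 1, reps = 1, m_solutions = 3,
#'                                swap_levels = c(0, 100, 300))
#' tr[, c("swaps_per_100", "normalized_median_sum", "mean_solution_distance")]
#' }
#' @export
randomization_trajectory <- function(n, k = 3, signed = FALSE,
                                     swap_levels = NULL,
                                     max_swaps_per_100 = 300, step = 25,
                                     reps = 5, m_solutions = 10, seed,
                                     mode = "exact", tau = 0.05,
                                     time_limit = 120) {
  if (is.null(swap_levels)) swap_levels <- seq(0, max_swaps_per_100, by = step)
  L <- length(swap_levels)
  seeds <- matrix(derive_seeds(seed, L * reps * (k + 1L)), ncol = k + 1L,
                  byrow = TRUE)  # row = (level, replicate); k genome seeds + solver seed
  rows <- vector("list", L * reps)
  idx <- 0L
  for (li in seq_len(L)) {
    s <- swap_levels[li]
    abs_swaps <- swaps_absolute(s, n)
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      gs <- lapply(seq_len(k), function(j) {
        set.seed(seeds[idx, j])
        swap_randomize(identity_genome(n, signed), abs_swaps)
      })
      inst <- median_instance(gs)
      rows[[idx]] <- tryCatch({
        sols <- sample_medians(inst, m_solutions, base_seed = seeds[idx, k + 1L],
                               mode = mode, time_limit = time_limit)
        trajectory_record(n, k, signed, s, r, m_solutions, sols, inst, tau)
      }, error = function(e)
        invalid_record(n, k, signed, s, r, m_solutions, conditionMessage(e)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(n = n, k = k, signed = signed,
                              swap_levels = swap_levels, reps = reps,
                              m_solutions = m_solutions, seed = seed,
                              mode = mode, tau = tau)
  out
}

#' Trajectories for several values of k
#'
#' Runs [randomization_trajectory()] once per entry of `k_values` with
#' independent sub-seeds and row-binds the records; convergence of the
#' saturated mean solution distance towards `(k - 1)/k` slows as k grows,
#' while the normalized median sum approaches `k - 1`.
#'
#' @param n gene count.
#' @param k_values integer vector of input counts, each >= 3.
#' @param seed master seed; each k gets an independently derived sub-seed.
#' @param ... passed to [randomization_trajectory()].
#' @return Row-bound records with the per-k configs in attribute `configs`.
#' @export
higher_k_trajectory <- function(n, k_values, seed, ...) {
  sub <- derive_seeds(seed, length(k_values))
  parts <- lapply(seq_along(k_values), function(i)
    randomization_trajectory(n, k = k_values[i], seed = sub[i], ...))
  cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(p) {
    for (cl in setdiff(cols, names(p))) p[[cl]] <- 0L
    p[cols]
  })
  out <- do.call(rbind, parts)
  attr(out, "configs") <- lapply(parts, attr, "config")
  out
}

#' Corner/middle census of median solutions for scrambled inputs
#'
#' For each genome size in `n_values` and each replicate, the k inputs are
#' generated with `swaps_per_100` random swaps per 100 genes (default 300,
#' deep in the saturated regime, so inputs retain almost no common
#' adjacencies), `m_solutions` optimal medians are sampled, and each is
#' classified as corner or middle. As n grows the middle fraction shrinks
#' while corner medians move ever closer to their nearest input.
#'
#' @param n_values integer vector of gene counts.
#' @param k number of inputs.
#' @param signed logical.
#' @param m_solutions medians sampled per instance.
#' @param reps replicates per genome size.
#' @param seed master seed (same derivation scheme as
#'   [randomization_trajectory()]).
#' @param swaps_per_100 randomization intensity.
#' @param tau spread threshold of [classify_median()].
#' @param mode,time_limit solver options.
#' @return A `data.frame`, one row per (n, replicate): `n`, `replicate`,
#'   `solutions_per_instance`, `middle_count`, `middle_fraction`,
#'   `mean_nearest_input_distance`, `valid`, plus `corner_1..corner_k`;
#'   config attached as attribute `config`.
#' @export
corner_middle_experiment <- function(n_values, k = 3, signed = FALSE,
                                     m_solutions = 50, reps = 5, seed,
                                     swaps_per_100 = 300, tau = 0.05,
                                     mode = "exact", time_limit = 120) {
  L <- length(n_values)
  seeds <- matrix(derive_seeds(seed, L * reps * (k + 1L)), ncol = k + 1L,
                  byrow = TRUE)
  rows <- vector("list", L * reps)
  idx <- 0L
  for (li in seq_len(L)) {
    n <- n_values[li]
    abs_swaps <- swaps_absolute(swaps_per_100, n)
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      gs <- lapply(seq_len(k), function(j) {
        set.seed(seeds[idx, j])
        swap_randomize(identity_genome(n, signed), abs_swaps)
      })
      inst <- median_instance(gs)
      rows[[idx]] <- tryCatch({
        sols <- sample_medians(inst, m_solutions, base_seed = seeds[idx, k + 1L],
                               mode = mode, time_limit = time_limit)
        rec <- trajectory_record(n, k, signed, swaps_per_100, r, m_solutions,
                                 sols, inst, tau)
        data.frame(n = n, replicate = r,
                   solutions_per_instance = m_solutions,
                   middle_count = rec$middle_count,
                   middle_fraction = rec$middle_count / m_solutions,
                   mean_nearest_input_distance = rec$mean_nearest_input_distance,
                   valid = TRUE,
                   rec[paste0("corner_", seq_len(k))])
      }, error = function(e) {
        rec <- data.frame(n = n, replicate = r,
                          solutions_per_instance = m_solutions,
                          middle_count = NA_integer_,
                          middle_fraction = NA_real_,
                          mean_nearest_input_distance = NA_real_,
                          valid = FALSE)
        for (i in seq_len(k)) rec[[paste0("corner_", i)]] <- NA_integer_
        warning("solver failure at n = ", n, ", replicate ", r, ": ",
                conditionMessage(e), call. = FALSE)
        rec
      })
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(n_values = n_values, k = k, signed = signed,
                              m_solutions = m_solutions, reps = reps,
                              seed = seed, swaps_per_100 = swaps_per_100,
                              tau = tau, mode = mode)
  out
}

#' Average the saturated tail of a trajectory
#'
#' Means of the normalized median sum and the inter-solution distance over
#' all valid records at or beyond `from` swaps per 100 genes -- well past
#' the knee of the saturation curve (around 50-60 swaps per 100 genes), so
#' the averages estimate the asymptotic plateau.
#'
#' @param records output of [randomization_trajectory()].
#' @param from lower edge of the saturation window (swaps per 100 genes).
#' @return A list: `normalized_median_sum`, `mean_solution_distance`,
#'   `records_used`.
#' @export
saturation_summary <- function(records, from = 150) {
  sat <- records[records$swaps_per_100 >= from & records$valid, , drop = FALSE]
  if (nrow(sat) == 0L) stop("no valid records at or beyond ", from, " swaps per 100 genes")
  list(normalized_median_sum = mean(sat$normalized_median_sum),
       mean_solution_distance = mean(sat$mean_solution_distance),
       records_used = nrow(sat))
}

format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

#' Export and re-import experiment records
#'
#' `summarize_and_export()` writes the records to `<path>.csv` (numeric
#' columns at full 17-digit precision, so a round trip through
#' `read_experiment_records()` reproduces every value exactly) and the
#' configuration -- seeds, solver mode, grids -- to the JSON sidecar
#' `<path>_config.json`.
#'
#' @param records a non-empty records `data.frame` from an experiment
#'   driver.
#' @param path output path prefix (no extension).
#' @return `summarize_and_export()`: paths of the files written,
#'   invisibly. `read_experiment_records()`: the records `data.frame` with
#'   the config re-attached.
#' @export
summarize_and_export <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame")
  csv <- paste0(path, ".csv")
  cfg <- paste0(path, "_config.json")
  printable <- as.data.frame(lapply(records, format_full),
                             stringsAsFactors = FALSE)
  names(printable) <- names(records)
  utils::write.csv(printable, csv, row.names = FALSE, quote = FALSE)
  config <- attr(records, "config")
  if (is.null(config)) config <- attr(records, "configs")
  jsonlite::write_json(list(config = config,
                            columns = lapply(records, class)),
                       cfg, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = csv, config = cfg))
}

#' @rdname summarize_and_export
#' @export
read_experiment_records <- function(path) {
  csv <- paste0(path, ".csv")
  cfg <- paste0(path, "_config.json")
  meta <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  classes <- vapply(meta$columns, function(cl) cl[[1L]], character(1))
  out <- utils::read.csv(csv, colClasses = classes)
  attr(out, "config") <- meta$config
  out
}

#' Plot a randomization trajectory
#'
#' Mean normalized median sum and mean inter-solution distance against
#' swaps per 100 genes, with the `k - 1` and `(k - 1)/k` asymptotes drawn
#' as dashed lines. Purely illustrative; all analyses use the record
#' values. Requires ggplot2.
#'
#' @param records output of [randomization_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectory <- function(records) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trajectory() needs the ggplot2 package")
  rec <- records[records$valid, ]
  agg <- stats::aggregate(
    cbind(normalized_median_sum, mean_solution_distance) ~ swaps_per_100 + k,
    data = rec, FUN = mean)
  long <- rbind(
    data.frame(swaps_per_100 = agg$swaps_per_100, k = agg$k,
               value = agg$normalized_median_sum, stat = "normalized median sum"),
    data.frame(swaps_per_100 = agg$swaps_per_100, k = agg$k,
               value = agg$mean_solution_distance, stat = "mean solution distance"))
  asym <- unique(rbind(
    data.frame(k = agg$k, stat = "normalized median sum", y = agg$k - 1),
    data.frame(k = agg$k, stat = "mean solution distance", y = (agg$k - 1) / agg$k)))
  ggplot2::ggplot(long, ggplot2::aes(x = swaps_per_100, y = value,
                                     colour = factor(k))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(data = asym,
                        ggplot2::aes(yintercept = y, colour = factor(k)),
                        linetype = "dashed", alpha = 0.5) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "swaps per 100 genes", y = NULL, colour = "k") +
    ggplot2::theme_minimal()
}
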