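#' Energy cutoff grid
#'
#' Pairwise interaction energies in PENs mostly fall between 0 and -35
#' kJ/mol, so the default grid scans that range in 1 kJ/mol steps. Grid
#' points are generated exactly as `start - i * step` to avoid
#' accumulation drift; half-integer grids (e.g. `step = 0.5` or
#' `start = -0.5`) are available to dodge ties with integer-valued
#' synthetic matrices.
#'
#' @param start least negative cutoff, kJ/mol (default 0).
#' @param stop most negative cutoff bound, kJ/mol (default -35).
#' @param step positive step magnitude, kJ/mol (default 1).
#' @return numeric vector of cutoffs, descending from `start`, all >= `stop`.
#' @export
cutoff_grid <- function(start = 0, stop = -35, step = 1) {
  if (!(start > stop)) abort("start must be greater (less negative) than stop")
  if (step <= 0) abort("step must be positive")
  start - step * seq.int(0L, floor((start - stop) / step + 1e-9))
}

.profile_metrics <- c("lcc", "clusters", "hubs", "cliques", "largest_community")

#' Sweep a network statistic over a cutoff grid
#'
#' Thresholds the PEN at every grid point (for the chosen energy channel)
#' and evaluates one network statistic on each PEN_e, exactly, producing
#' the statistic's transition/population profile as a function of e.
#' Available metrics: `"lcc"` (largest-connected-component size),
#' `"clusters"` (components of size >= `min_size`), `"hubs"` (nodes of
#' degree >= `degree_threshold`), `"cliques"` (number of k-cliques) and
#' `"largest_community"` (largest k-clique-percolation community size).
#'
#' @param p a `pen` or [energy_matrix()].
#' @param metric which statistic to profile.
#' @param channel energy channel defining edges.
#' @param grid cutoff grid from [cutoff_grid()].
#' @param k clique size for the clique metrics (>= 3 for communities).
#' @param min_size minimum cluster size for `"clusters"`.
#' @param degree_threshold minimum degree for `"hubs"`.
#' @return a `pen_profile`: a tibble with columns `e` (kJ/mol, descending)
#'   and `value` (non-negative integer), carrying `metric`, `channel`, and
#'   parameter attributes.
#' @export
sweep_profile <- function(p, metric = .profile_metrics,
                          channel = c("total", "lj", "coulomb"),
                          grid = cutoff_grid(), k = 3, min_size = 3,
                          degree_threshold = 4) {
  metric <- match.arg(metric)
  channel <- match.arg(channel)
  if (inherits(p, "energy_matrix")) p <- build_pen(p)
  if (metric == "largest_community" && k < 3) {
    abort("largest_community requires k >= 3")
  }
  if (metric == "cliques" && k < 2) abort("cliques requires k >= 2")
  fn <- switch(metric,
    lcc = function(g) lcc_size(g),
    clusters = function(g) count_clusters(g, min_size = min_size),
    hubs = function(g) length(hubs(g, degree_threshold = degree_threshold)),
    cliques = function(g) length(enumerate_k_cliques(g, k = k)),
    largest_community = function(g) largest_community_size(g, k = k)
  )
  values <- vapply(grid, function(e) {
    as.integer(fn(threshold_pen(p, e, channel = channel)))
  }, 1L)
  new_pen_profile(grid, values, metric = metric, channel = channel,
                  k = k, min_size = min_size,
                  degree_threshold = degree_threshold)
}

new_pen_profile <- function(e, value, metric, channel, k = NA_integer_,
                            min_size = NA_integer_,
                            degree_threshold = NA_integer_) {
  out <- tibble(e = as.numeric(e), value = as.integer(value))
  attr(out, "metric") <- metric
  attr(out, "channel") <- channel
  attr(out, "k") <- k
  attr(out, "min_size") <- min_size
  attr(out, "degree_threshold") <- degree_threshold
  class(out) <- c("pen_profile", class(out))
  out
}

#' Transition bracket of an LCC profile
#'
#' A convenience summary of where the network falls apart: `e_hi` is the
#' most negative grid cutoff at which the LCC still holds at least
#' `hi_frac` of its maximum, and `e_lo` the least negative cutoff at which
#' it has dropped to at most `lo_frac` of the maximum. Grid values are
#' returned as-is, with no interpolation.
#'
#' @param s a `pen_profile` with a positive maximum (typically metric
#'   `"lcc"`).
#' @param hi_frac,lo_frac fractions of the profile maximum.
#' @return named list with `e_hi` and `e_lo` (kJ/mol).
#' @export
transition_width <- function(s, hi_frac = 0.9, lo_frac = 0.1) {
  stopifnot(inherits(s, "pen_profile"))
  mx <- max(s$value)
  if (mx <= 0) abort("transition undefined: profile is all zero")
  hi <- s$e[s$value >= hi_frac * mx]
  lo <- s$e[s$value <= lo_frac * mx]
  if (!length(lo)) {
    abort("transition undefined: profile never falls to the low fraction")
  }
  list(e_hi = min(hi), e_lo = max(lo))
}

#' Peak of a profile
#'
#' Maximum value of a profile and the cutoff where it occurs; ties are
#' broken toward the least negative e (the first grid point, since grids
#' descend).
#'
#' @param s a `pen_profile`.
#' @return named list with `e_peak` (kJ/mol) and `value_peak` (integer).
#' @export
profile_peak <- function(s) {
  stopifnot(inherits(s, "pen_profile"), nrow(s) > 0)
  i <- which.max(s$value)  # first max in descending-e order
  list(e_peak = s$e[i], value_peak = s$value[i])
}

#' Write / read a profile as TSV
#'
#' Two tab-separated columns `e` (kJ/mol, 3 decimals, descending from 0
#' toward negative) and `value`, preceded by comment lines recording the
#' metric, channel and parameters so the profile can be re-read intact.
#'
#' @param p a `pen_profile`.
#' @param path file path.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "pen_profile"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", attr(p, "metric")), con)
  writeLines(sprintf("# channel: %s", attr(p, "channel")), con)
  writeLines(sprintf("# k: %s", attr(p, "k")), con)
  writeLines(sprintf("# min_size: %s", attr(p, "min_size")), con)
  writeLines(sprintf("# degree_threshold: %s", attr(p, "degree_threshold")), con)
  writeLines("e\tvalue", con)
  if (nrow(p)) {
    writeLines(sprintf("%.3f\t%d", p$e, p$value), con)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^# *([a-z_]+): *(.*)$", ln))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"))
  if (!all(c("e", "value") %in% names(df))) {
    abort(sprintf("profile file '%s' must have columns e and value", path))
  }
  as_int <- function(x) if (is.null(x) || x == "NA") NA_integer_ else as.integer(x)
  new_pen_profile(df$e, df$value,
                  metric = meta$metric %||% "unknown",
                  channel = meta$channel %||% "total",
                  k = as_int(meta$k), min_size = as_int(meta$min_size),
                  degree_threshold = as_int(meta$degree_threshold))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
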