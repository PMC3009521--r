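#' Compare two proteins' network profiles
#'
#' Takes matching sets of profiles for two proteins (e.g. a thermophile
#' and its mesophilic homolog) and reports, per metric: peak height and
#' position of each profile, the LCC transition bracket when an LCC
#' profile is present, the summed counts in the high-energy region
#' (cutoffs below -20 kJ/mol, where electrostatics dominate), and the
#' point-by-point signed difference series (first minus second). The
#' report is purely numeric: it draws no stability verdicts.
#'
#' @param a,b a `pen_profile` or a list of them; metrics/channels must
#'   match pairwise and every pair must share an identical cutoff grid.
#' @param labels length-2 character labels for the two proteins.
#' @param high_energy_below cutoff (kJ/mol) delimiting the high-energy
#'   region; grid points strictly below it are summed.
#' @return an object of class `pen_comparison` with elements `labels`,
#'   `summary` (tibble: metric, channel, statistic, value for each side,
#'   difference), `differences` (tibble: metric, channel, e, value_a,
#'   value_b, diff) and the input `profiles`.
#' @export
compare_pair <- function(a, b, labels = c("a", "b"), high_energy_below = -20) {
  if (inherits(a, "pen_profile")) a <- list(a)
  if (inherits(b, "pen_profile")) b <- list(b)
  stopifnot(length(a) == length(b), length(labels) == 2)
  key <- function(p) paste(attr(p, "metric"), attr(p, "channel"), attr(p, "k"))
  ka <- vapply(a, key, ""); kb <- vapply(b, key, "")
  if (!setequal(ka, kb) || anyDuplicated(ka)) {
    abort("profiles of `a` and `b` must match one-to-one by metric/channel/k")
  }
  b <- b[match(ka, kb)]

  diffs <- list(); summaries <- list()
  for (ix in seq_along(a)) {
    pa <- a[[ix]]; pb <- b[[ix]]
    if (!isTRUE(all.equal(pa$e, pb$e, tolerance = 0))) {
      abort(sprintf("grid mismatch for metric '%s'", attr(pa, "metric")))
    }
    metric <- attr(pa, "metric"); chan <- attr(pa, "channel")
    diffs[[ix]] <- tibble(
      metric = metric, channel = chan, e = pa$e,
      value_a = pa$value, value_b = pb$value,
      diff = pa$value - pb$value
    )
    pk_a <- profile_peak(pa); pk_b <- profile_peak(pb)
    he <- pa$e < high_energy_below
    stat <- function(statistic, va, vb) {
      tibble(metric = metric, channel = chan, statistic = statistic,
             value_a = va, value_b = vb, difference = va - vb)
    }
    rows <- list(
      stat("peak_value", pk_a$value_peak, pk_b$value_peak),
      stat("peak_e", pk_a$e_peak, pk_b$e_peak),
      stat("high_energy_total", sum(pa$value[he]), sum(pb$value[he]))
    )
    if (metric == "lcc") {
      tw <- function(p) tryCatch(transition_width(p),
                                 error = function(e) list(e_hi = NA_real_, e_lo = NA_real_))
      ta <- tw(pa); tb <- tw(pb)
      rows <- c(rows, list(stat("transition_e_hi", ta$e_hi, tb$e_hi),
                           stat("transition_e_lo", ta$e_lo, tb$e_lo)))
    }
    summaries[[ix]] <- dplyr::bind_rows(rows)
  }
  structure(
    list(labels = labels,
         summary = dplyr::bind_rows(summaries),
         differences = dplyr::bind_rows(diffs),
         profiles = list(a = a, b = b),
         high_energy_below = high_energy_below),
    class = "pen_comparison"
  )
}

#' @export
print.pen_comparison <- function(x, ...) {
  cat(sprintf("<pen_comparison> %s vs %s, %d metric(s)\n",
              x$labels[1], x$labels[2], length(x$profiles$a)))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Write a comparison report as TSV
#'
#' One row per (metric, channel, summary statistic), with one value column
#' per protein and their signed difference.
#'
#' @param report a `pen_comparison`.
#' @param path output file path.
#' @export
write_comparison <- function(report, path) {
  stopifnot(inherits(report, "pen_comparison"))
  df <- as.data.frame(report$summary)
  names(df)[names(df) == "value_a"] <- report$labels[1]
  names(df)[names(df) == "value_b"] <- report$labels[2]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], .fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a comparison report
#'
#' @param x a `pen_comparison`.
#' @param ... unused.
#' @return the long summary tibble, one row per (metric, channel,
#'   statistic).
#' @method tidy pen_comparison
#' @export
tidy.pen_comparison <- function(x, ...) x$summary

#' @rdname tidy.pen_comparison
#' @method glance pen_comparison
#' @export
glance.pen_comparison <- function(x, ...) {
  tibble(
    label_a = x$labels[1], label_b = x$labels[2],
    n_metrics = length(x$profiles$a),
    grid_min = min(x$differences$e), grid_max = max(x$differences$e),
    max_abs_diff = max(abs(x$differences$diff))
  )
}

#' Tidy a thresholded PEN into an edge table
#'
#' @param x a `pen_graph`.
#' @param ... unused.
#' @return tibble with one row per edge (`from`, `to` residue labels).
#' @method tidy pen_graph
#' @export
tidy.pen_graph <- function(x, ...) {
  ut <- which(x$adjacency & upper.tri(x$adjacency), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  tibble(from = x$residues$label[ut[, 1]], to = x$residues$label[ut[, 2]])
}

#' @rdname tidy.pen_graph
#' @method glance pen_graph
#' @export
glance.pen_graph <- function(x, ...) {
  tibble(
    cutoff = x$cutoff, channel = x$channel,
    n_nodes = nrow(x$residues), n_edges = edge_count(x),
    lcc = lcc_size(x), n_clusters = count_clusters(x),
    n_hubs = length(hubs(x))
  )
}
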