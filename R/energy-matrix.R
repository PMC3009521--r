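#' Construct a residue-pair energy matrix
#'
#' An `energy_matrix` holds symmetric residue-by-residue interaction
#' energies in kJ/mol, split into a Lennard-Jones channel (`lj`), a Coulomb
#' channel (`coulomb`) and their sum (`total`). Channels other than `total`
#' may be absent (`NULL`), e.g. when a file carries only total energies.
#' The diagonal is zero by definition and pairs excluded from the energy
#' computation (sequence-adjacent neighbours, by default) carry zero in all
#' channels and are flagged in the logical `excluded` mask so thresholding
#' never turns them into edges.
#'
#' @param residues residue table ([residue_table()]).
#' @param total,lj,coulomb symmetric n x n numeric matrices (kJ/mol);
#'   `lj`/`coulomb` may be `NULL`. If `total` is `NULL` it is computed as
#'   `lj + coulomb`.
#' @param excluded optional n x n logical mask of pairs excluded by policy.
#' @param tol symmetry tolerance in kJ/mol.
#' @return an object of class `energy_matrix`.
#' @export
energy_matrix <- function(residues, total = NULL, lj = NULL, coulomb = NULL,
                          excluded = NULL, tol = 1e-6) {
  n <- nrow(residues)
  if (is.null(total)) {
    if (is.null(lj) || is.null(coulomb)) {
      abort("need `total`, or both `lj` and `coulomb`")
    }
    total <- lj + coulomb
  }
  .check_channel <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == c(n, n))) abort(sprintf("`%s` must be %d x %d", what, n, n))
    d <- abs(m - t(m))
    if (any(d > tol)) {
      ij <- which(d == max(d), arr.ind = TRUE)[1, ]
      abort(sprintf("`%s` is asymmetric at pair (%s, %s): %g vs %g", what,
                    residues$label[ij[1]], residues$label[ij[2]],
                    m[ij[1], ij[2]], m[ij[2], ij[1]]))
    }
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(residues$label, residues$label)
    m
  }
  total <- .check_channel(total, "total")
  lj <- .check_channel(lj, "lj")
  coulomb <- .check_channel(coulomb, "coulomb")
  if (is.null(excluded)) excluded <- matrix(FALSE, n, n)
  excluded <- excluded | t(excluded)
  diag(excluded) <- FALSE
  structure(
    list(residues = residues, total = total, lj = lj, coulomb = coulomb,
         excluded = excluded),
    class = "energy_matrix"
  )
}

#' @export
print.energy_matrix <- function(x, ...) {
  ch <- c("total", if (!is.null(x$lj)) "lj", if (!is.null(x$coulomb)) "coulomb")
  cat(sprintf("<energy_matrix> %d residues, channels: %s\n",
              nrow(x$residues), paste(ch, collapse = ", ")))
  cat(sprintf("  total range [%.3f, %.3f] kJ/mol\n",
              min(x$total), max(x$total)))
  invisible(x)
}

#' Channels present in an energy matrix or PEN
#' @param x an `energy_matrix` or `pen`.
#' @return character vector among `"total"`, `"lj"`, `"coulomb"`.
#' @export
channels <- function(x) {
  c("total", if (!is.null(x$lj)) "lj", if (!is.null(x$coulomb)) "coulomb")
}

#' Read a residue-pair energy matrix from TSV
#'
#' Two dialects are supported. `layout = "square"` is a full symmetric
#' matrix with residue labels as header row and first column, carrying a
#' single channel (named by `channel`). `layout = "pairs"` is a long-form
#' pair list with columns `i`, `j` (residue labels) and one or more of
#' `lj`, `coulomb`, `total`; unordered pairs appear at most once and pairs
#' not listed are taken as zero energy (no interaction). Energies are
#' kJ/mol throughout; no unit autodetection is performed.
#'
#' @param path TSV file path.
#' @param layout `"pairs"` or `"square"`.
#' @param channel for square layout, which channel the matrix carries.
#' @param residues optional residue universe for the pairs layout (a
#'   residue table or character vector of labels); residues absent from
#'   every listed pair then still appear in the matrix, with zero energy
#'   to every partner. Defaults to the labels seen in the file.
#' @param tol symmetry tolerance in kJ/mol for the square layout.
#' @return an [energy_matrix()].
#' @export
read_energy_matrix <- function(path, layout = c("pairs", "square"),
                               channel = "total", residues = NULL,
                               tol = 1e-6) {
  layout <- match.arg(layout)
  if (layout == "square") {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    labels <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    if (any(is.na(m))) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      abort(sprintf("non-numeric cell at row %d, column %d in '%s'",
                    bad[1], bad[2], path))
    }
    if (!identical(colnames(m), labels)) {
      abort(sprintf("row and column labels disagree in '%s'", path))
    }
    res <- .parse_residue_labels(labels)
    args <- list(residues = res, tol = tol)
    args[[channel]] <- m
    if (channel != "total") {
      # single off-total channel: total unknown; treat channel as total too
      abort("square layout carries the `total` channel; use pairs layout for lj/coulomb")
    }
    do.call(energy_matrix, args)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    need <- intersect(c("lj", "coulomb", "total"), names(df))
    if (!all(c("i", "j") %in% names(df)) || length(need) == 0) {
      abort(sprintf("pairs layout needs columns i, j and at least one of lj/coulomb/total in '%s'", path))
    }
    labels <- unique(c(df$i, df$j))
    if (!is.null(residues)) {
      universe <- if (is.character(residues)) residues else residues$label
      missing_lab <- setdiff(labels, universe)
      if (length(missing_lab)) {
        abort(sprintf("pair label(s) outside the residue universe: %s",
                      paste(missing_lab, collapse = ", ")))
      }
      labels <- universe
    }
    # residue order: by parsed (chain, seq_number) when labels parse
    res <- .parse_residue_labels(labels)
    ord <- order(res$chain, res$seq_number,
                 ifelse(is.na(res$insertion_code), "", res$insertion_code))
    res <- res[ord, , drop = FALSE]
    res$index <- seq_len(nrow(res))
    n <- nrow(res)
    ii <- match(df$i, res$label)
    jj <- match(df$j, res$label)
    key <- paste(pmin(ii, jj), pmax(ii, jj))
    vals <- list()
    for (ch in need) {
      v <- suppressWarnings(as.numeric(df[[ch]]))
      if (any(is.na(v) & df[[ch]] != "NA")) {
        abort(sprintf("non-numeric value in column '%s' of '%s'", ch, path))
      }
      if (anyDuplicated(key)) {
        dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
        agg <- tapply(v[dup], key[dup], function(z) diff(range(z)))
        if (any(agg > 1e-9)) {
          abort(sprintf("conflicting duplicate pair values in '%s' (pair %s)",
                        path, names(agg)[which(agg > 1e-9)[1]]))
        }
      }
      m <- matrix(0, n, n)
      m[cbind(ii, jj)] <- v
      m[cbind(jj, ii)] <- v
      vals[[ch]] <- m
    }
    energy_matrix(res,
                  total = vals$total,
                  lj = vals$lj, coulomb = vals$coulomb, tol = tol)
  }
}

#' Write a residue-pair energy matrix to TSV
#'
#' The pairs layout writes one row per unordered residue pair with a
#' non-zero value in any present channel; the square layout writes the
#' full symmetric `total` matrix with residue labels.
#'
#' @param m an [energy_matrix()].
#' @param path output file path.
#' @param layout `"pairs"` or `"square"`.
#' @export
write_energy_matrix <- function(m, path, layout = c("pairs", "square")) {
  layout <- match.arg(layout)
  stopifnot(inherits(m, "energy_matrix"))
  n <- nrow(m$residues)
  if (layout == "square") {
    df <- data.frame(label = m$residues$label, m$total, check.names = FALSE)
    names(df)[1] <- "label"
    colnames(df)[-1] <- m$residues$label
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ut <- which(upper.tri(m$total), arr.ind = TRUE)
    chs <- channels(m)
    keep <- Reduce(`|`, lapply(chs, function(ch) m[[ch]][ut] != 0))
    ut <- ut[keep, , drop = FALSE]
    df <- data.frame(i = m$residues$label[ut[, 1]],
                     j = m$residues$label[ut[, 2]])
    for (ch in chs) df[[ch]] <- .fmt_num(m[[ch]][ut])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# full-precision decimal formatting for round-trippable TSV output;
# trailing zeros are stripped only after a decimal point
.fmt_num <- function(x) {
  s <- vapply(x, function(v) format(v, digits = 17, scientific = FALSE), "")
  has_dec <- grepl("\\.", s)
  s[has_dec] <- sub("0+$", "", s[has_dec])
  sub("\\.$", "", s)
}
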