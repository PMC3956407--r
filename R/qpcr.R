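# qPCR relative quantification: per-well amplification efficiency from
# raw fluorescence (window-of-linearity fit), reference-gene normalized
# quantities, between-group expression ratios, and a label-permutation
# significance test on log-ratios.

#' Estimate amplification efficiency from a fluorescence curve
#'
#' Subtracts a baseline (mean signal of the first \code{baseline_cycles}
#' cycles), then finds the contiguous window of \code{window} cycles with
#' all-positive corrected signal whose log-linear fit has maximal R
#' squared; the efficiency is \code{10^slope} of that fit (per-cycle
#' amplification factor, 2 = perfect doubling).
#'
#' @param cycle integer vector of cycle numbers, strictly increasing.
#' @param signal positive fluorescence readings, same length.
#' @param window number of points in the window of linearity (default 4).
#' @param baseline_cycles cycles averaged for the baseline (default 3).
#' @return estimated efficiency in (1, 2].
#' @export
#' @examples
#' cyc <- 1:35
#' estimate_efficiency(cyc, 0.01 * 2^cyc)
estimate_efficiency <- function(cycle, signal, window = 4L,
                                baseline_cycles = 3L) {
  stopifnot(length(cycle) == length(signal),
            length(cycle) >= window + 2L, all(diff(cycle) > 0))
  corrected <- signal - mean(signal[seq_len(baseline_cycles)])
  n <- length(cycle)
  best_r2 <- -Inf
  best_slope <- NA_real_
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    y <- corrected[idx]
    if (any(y <= 0)) next
    fit <- stats::lm(log10(y) ~ cycle[idx])
    r2 <- summary(fit)$r.squared
    if (is.finite(r2) && r2 > best_r2) {
      best_r2 <- r2
      best_slope <- unname(stats::coef(fit)[2])
    }
  }
  if (!is.finite(best_r2)) {
    stop("no window of ", window, " cycles with positive baseline-corrected ",
         "signal; cannot estimate efficiency")
  }
  e <- 10^best_slope
  if (e <= 1) stop("estimated efficiency <= 1 (no amplification detected)")
  min(e, 2)
}

#' Reference-normalized transcript quantity
#'
#' The quantity of target transcript relative to the reference gene at a
#' fixed detection threshold: \code{Q = e_target^(-ct_target) /
#' e_ref^(-ct_ref)} (efficiency-corrected; with both efficiencies 2 this
#' is the familiar 2^-dCt).
#'
#' @param ct_target,ct_ref quantification cycles (vectorised).
#' @param e_target,e_ref amplification efficiencies in (1, 2].
#' @return positive numeric vector.
#' @export
#' @examples
#' normalized_quantity(20, 2, 15, 2)  # 2^-5
normalized_quantity <- function(ct_target, e_target, ct_ref, e_ref) {
  if (any(e_target <= 1 | e_target > 2) || any(e_ref <= 1 | e_ref > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  if (any(ct_target <= 0) || any(ct_ref <= 0)) stop("Ct values must be positive")
  e_target^(-ct_target) / e_ref^(-ct_ref)
}

# run expr with a private, restored RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Between-group expression ratio with permutation significance
#'
#' Computes per-replicate reference-normalized quantities Q for one
#' target gene (replicates paired with reference wells by group and
#' replicate index), the group means Q_A and Q_B, their ratio
#' R = Q_A / Q_B with a first-order propagated standard error, and a
#' group-label permutation p-value on |log R| (exhaustive when at most
#' \code{max_exhaustive} distinct label assignments exist, otherwise
#' sampled with the mandatory seed and the (k+1)/(n+1) small-sample
#' correction).
#'
#' @param wells data.frame with columns \code{gene}, \code{group}
#'   ("A"/"B"), \code{replicate}, \code{ct} and optionally
#'   \code{efficiency}; must contain the target and the reference gene.
#' @param gene target gene name.
#' @param reference reference gene name (default \code{"GAPDH"}).
#' @param n_perm number of sampled permutations (>= 1000).
#' @param seed RNG seed for sampled permutations (mandatory).
#' @param default_efficiency efficiency used where the \code{efficiency}
#'   column is absent or NA (default 2, perfect doubling).
#' @param max_exhaustive enumerate all assignments when their number is
#'   at most this (default 10000).
#' @return object of class \code{"qpcr_ratio"}: list with \code{gene},
#'   \code{Q_A}, \code{Q_B}, \code{R}, \code{se_R}, \code{p_perm},
#'   \code{n_A}, \code{n_B}, \code{perm_method}, \code{q_replicates}.
#' @export
expression_ratio <- function(wells, gene, reference = "GAPDH",
                             n_perm = 10000L, seed,
                             default_efficiency = 2,
                             max_exhaustive = 10000L) {
  stopifnot(is.data.frame(wells),
            all(c("gene", "group", "replicate", "ct") %in% names(wells)),
            n_perm >= 1000)
  if (missing(seed)) stop("an explicit seed is required for the permutation test")
  eff <- function(df) {
    if ("efficiency" %in% names(df)) {
      ifelse(is.na(df$efficiency), default_efficiency, df$efficiency)
    } else rep(default_efficiency, nrow(df))
  }
  tgt <- wells[wells$gene == gene, , drop = FALSE]
  ref <- wells[wells$gene == reference, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no wells for target gene '", gene, "'")
  if (nrow(ref) == 0) stop("no wells for reference gene '", reference, "'")
  key <- function(df) paste(df$group, df$replicate, sep = ":")
  if (anyDuplicated(key(tgt)) || anyDuplicated(key(ref))) {
    stop("duplicate (group, replicate) wells for a single gene")
  }
  if (!setequal(key(tgt), key(ref))) {
    stop("target and reference wells are not paired: every (group, replicate) ",
         "must appear in both")
  }
  ref <- ref[match(key(tgt), key(ref)), , drop = FALSE]
  q <- normalized_quantity(tgt$ct, eff(tgt), ref$ct, eff(ref))
  grp <- tgt$group
  n_A <- sum(grp == "A"); n_B <- sum(grp == "B")
  if (n_A < 2 || n_B < 2) stop("need at least 2 replicates per group")
  Q_A <- mean(q[grp == "A"]); Q_B <- mean(q[grp == "B"])
  se_A <- stats::sd(q[grp == "A"]) / sqrt(n_A)
  se_B <- stats::sd(q[grp == "B"]) / sqrt(n_B)
  R <- Q_A / Q_B
  se_R <- R * sqrt((se_A / Q_A)^2 + (se_B / Q_B)^2)
  obs <- abs(log(R))
  n <- n_A + n_B
  # statistic for a label assignment: |log(mean Q_A' / mean Q_B')|
  stat_for <- function(idx_A) {
    abs(log(mean(q[idx_A]) / mean(q[-idx_A])))
  }
  n_assign <- choose(n, n_A)
  tol <- 1e-12
  if (n_assign <= max_exhaustive) {
    combs <- utils::combn(n, n_A)
    stats_all <- apply(combs, 2, stat_for)
    p_perm <- mean(stats_all >= obs - tol)
    method <- "exhaustive"
  } else {
    stats_all <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_for(sample.int(n, n_A)),
             numeric(1))
    })
    p_perm <- (sum(stats_all >= obs - tol) + 1) / (n_perm + 1)
    method <- "sampled"
  }
  structure(list(gene = gene, Q_A = Q_A, Q_B = Q_B, R = R, se_R = se_R,
                 p_perm = p_perm, n_A = n_A, n_B = n_B,
                 perm_method = method, q_replicates = q),
            class = "qpcr_ratio")
}

#' @export
print.qpcr_ratio <- function(x, ...) {
  cat(sprintf("qPCR relative expression: %s\n", x$gene))
  cat(sprintf("  Q_A = %.4g, Q_B = %.4g (n = %d, %d)\n",
              x$Q_A, x$Q_B, x$n_A, x$n_B))
  cat(sprintf("  R = Q_A/Q_B = %.4g +/- %.2g, permutation p = %.4g (%s)\n",
              x$R, x$se_R, x$p_perm, x$perm_method))
  invisible(x)
}

#' Expression ratios for every target gene in a wells table
#'
#' @inheritParams expression_ratio
#' @return data.frame with one row per target gene: \code{gene},
#'   \code{Q_A}, \code{Q_B}, \code{R}, \code{se_R}, \code{p_perm}.
#' @export
qpcr_ratios <- function(wells, reference = "GAPDH", n_perm = 10000L, seed,
                        default_efficiency = 2) {
  genes <- setdiff(unique(wells$gene), reference)
  rows <- lapply(genes, function(g) {
    r <- expression_ratio(wells, g, reference = reference, n_perm = n_perm,
                          seed = seed, default_efficiency = default_efficiency)
    data.frame(gene = g, Q_A = r$Q_A, Q_B = r$Q_B, R = r$R, se_R = r$se_R,
               p_perm = r$p_perm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fill per-well efficiencies from fluorescence curves
#'
#' @param wells qPCR wells data.frame.
#' @param curves data.frame with columns \code{gene}, \code{group},
#'   \code{replicate}, \code{cycle}, \code{signal}.
#' @param window window-of-linearity length passed to
#'   \code{\link{estimate_efficiency}}.
#' @return \code{wells} with an \code{efficiency} column estimated from
#'   each well's curve (wells without a curve keep their value, or NA).
#' @export
wells_with_efficiency <- function(wells, curves, window = 4L) {
  if (!"efficiency" %in% names(wells)) wells$efficiency <- NA_real_
  wkey <- paste(wells$gene, wells$group, wells$replicate, sep = ":")
  ckey <- paste(curves$gene, curves$group, curves$replicate, sep = ":")
  for (i in seq_along(wkey)) {
    sel <- ckey == wkey[i]
    if (any(sel)) {
      cc <- curves[sel, , drop = FALSE]
      cc <- cc[order(cc$cycle), , drop = FALSE]
      wells$efficiency[i] <- estimate_efficiency(cc$cycle, cc$signal,
                                                 window = window)
    }
  }
  wells
}

#' Read qPCR wells / curves tables from TSV
#'
#' @param path file path. Wells: columns gene, group, replicate, ct and
#'   optional efficiency. Curves: gene, group, replicate, cycle, signal.
#' @return data.frame.
#' @export
read_qpcr_wells <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "group", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("wells table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!df$group %in% c("A", "B"))) stop("group must be 'A' or 'B'")
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  df
}

#' @rdname read_qpcr_wells
#' @export
read_qpcr_curves <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "group", "replicate", "cycle", "signal")
  if (!all(need %in% names(df))) {
    stop("curves table must have columns: ", paste(need, collapse = ", "))
  }
  df
}
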