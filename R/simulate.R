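# Synthetic-data generators: paired tag libraries with planted
# differential expression, concatemer FASTA realizing those libraries,
# and qPCR wells/curves with known efficiencies and ratios. Every
# generator takes an explicit seed; there is no implicit randomness.

#' Simulation configuration for paired SAGE tag libraries
#'
#' Defaults emulate a shallow two-library SAGE comparison: 250 sequenced
#' clones of ~8 ditags each per library, giving library totals of 1894
#' and 2670 tags, a log-normal transcript-abundance distribution (SAGE
#' libraries are classically dominated by a few high-abundance
#' transcripts), and a small planted differentially expressed fraction
#' with symmetric up/down fold changes.
#'
#' @param n_transcripts catalogue size (unique transcripts/tags).
#' @param abundance_log_mean,abundance_log_sd log-normal abundance
#'   parameters (meanlog is arbitrary since proportions are normalized;
#'   sdlog controls skew).
#' @param de_fraction fraction of transcripts planted as differentially
#'   expressed, in [0, 1).
#' @param fold_changes fold changes cycled over the planted transcripts
#'   (applied to library-B abundance; values > 1 are B-enriched).
#' @param total_A,total_B library tag totals.
#' @param tags_per_clone ditags concatenated per sequenced clone.
#' @param seed mandatory RNG seed.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_transcripts = 3000L, abundance_log_mean = 0,
                       abundance_log_sd = 2, de_fraction = 0.02,
                       fold_changes = c(5, 1 / 5), total_A = 1894L,
                       total_B = 2670L, tags_per_clone = 8L, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_transcripts >= 1, de_fraction >= 0, de_fraction < 1,
            all(fold_changes > 0), total_A >= 1, total_B >= 1,
            tags_per_clone >= 1, abundance_log_sd >= 0)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd,
                 de_fraction = de_fraction,
                 fold_changes = fold_changes,
                 total_A = as.integer(total_A),
                 total_B = as.integer(total_B),
                 tags_per_clone = as.integer(tags_per_clone),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# random 17-mers whose 21-bp tag (CATG + 17-mer) contains CATG only at
# the anchor. Endings "CA" and "CAT" are also excluded: in a ditag core
# t + revcomp(u), a junction CATG requires the left 17-mer to end in
# "C", "CA" or "CAT" with the complementary start on the right, and the
# right side can only supply it if the partner's 17-mer ends in "CAT" or
# "CA"; banning those two endings therefore makes every pairing
# junction-clash-free, so simulated concatemers carry anchors only
# between cores and extraction inverts generation exactly
random_tag_catalog <- function(n) {
  tags <- character(0)
  attempts <- 0L
  while (length(tags) < n) {
    attempts <- attempts + 1L
    if (attempts > 100L * n) stop("failed to draw ", n, " unique tags")
    m <- n - length(tags)
    draw <- vapply(seq_len(m), function(i) {
      paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")
    }, character(1))
    cand <- paste0(ANCHOR, draw)
    ok <- !grepl(ANCHOR, substring(cand, 2L), fixed = TRUE) &
      substring(cand, 20L, 21L) != "CA" & substring(cand, 19L, 21L) != "CAT"
    tags <- unique(c(tags, cand[ok]))
  }
  tags[seq_len(n)]
}

#' Simulate ground-truth tag abundances with planted DE
#'
#' Draws a unique CATG-anchored tag catalogue, log-normal abundances
#' normalized to proportions, and plants differential expression in a
#' \code{de_fraction} of transcripts by multiplying their library-B
#' abundance by the assigned fold change (fold changes cycled,
#' renormalized). Fully reproducible from the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame of class \code{"sim_truth"}: columns \code{tag},
#'   \code{abundance_A}, \code{abundance_B}, \code{is_de},
#'   \code{fold_change}; the config is attached as attribute
#'   \code{"config"}.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_transcripts
    tag <- random_tag_catalog(n)
    a <- stats::rlnorm(n, config$abundance_log_mean, config$abundance_log_sd)
    p_A <- a / sum(a)
    n_de <- round(config$de_fraction * n)
    is_de <- rep(FALSE, n)
    fc <- rep(1, n)
    if (n_de > 0) {
      idx <- sample.int(n, n_de)
      is_de[idx] <- TRUE
      fc[idx] <- rep_len(config$fold_changes, n_de)
    }
    b <- a * fc
    p_B <- b / sum(b)
    out <- data.frame(tag = tag, abundance_A = p_A, abundance_B = p_B,
                      is_de = is_de, fold_change = fc,
                      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    class(out) <- c("sim_truth", "data.frame")
    out
  })
}

#' Sample paired tag libraries from a simulated truth
#'
#' Counts are drawn multinomially per library at the configured totals
#' (the null model of equal expression corresponds to identical
#' proportions in both libraries). Tags unobserved in both libraries are
#' dropped from the table.
#'
#' @param truth a \code{\link{simulate_truth}} result.
#' @param seed RNG seed for the multinomial draws (defaults to the
#'   config seed + 1 so truth and sampling streams are distinct).
#' @param labels library names.
#' @return a \code{\link{tag_count_table}} whose totals equal the
#'   configured totals exactly.
#' @export
sample_libraries <- function(truth, seed = attr(truth, "config")$seed + 1L,
                             labels = c("library_A", "library_B")) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- attr(truth, "config")
  with_seed(seed, {
    cA <- as.integer(stats::rmultinom(1, config$total_A, truth$abundance_A))
    cB <- as.integer(stats::rmultinom(1, config$total_B, truth$abundance_B))
    keep <- cA + cB > 0
    tag_count_table(truth$tag[keep], cA[keep], cB[keep], labels = labels)
  })
}

# ditag core for an ordered tag pair: first tag forward, second tag
# reverse-complemented (tail-to-tail ligation), 34 bp
ditag_core <- function(tag1, tag2) {
  paste0(substring(tag1, 5L, 21L), revcomp(substring(tag2, 5L, 21L)))
}

# pair off a shuffled tag multiset into anchor-free cores; when a
# junction would create an internal CATG, deterministically swap the
# partner with a later unpaired tag (the tag multiset is preserved)
pair_into_cores <- function(tags) {
  n <- length(tags)
  stopifnot(n %% 2 == 0)
  cores <- character(n / 2)
  i <- 1L
  while (i < n) {
    placed <- FALSE
    for (j in (i + 1L):n) {
      core <- ditag_core(tags[i], tags[j])
      if (!grepl(ANCHOR, core, fixed = TRUE)) {
        if (j != i + 1L) {
          tmp <- tags[i + 1L]; tags[i + 1L] <- tags[j]; tags[j] <- tmp
        }
        cores[(i + 1L) / 2L] <- core
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)  # stuck (typically at the final pair)
    i <- i + 2L
  }
  cores
}

# shuffle-and-pair with bounded deterministic retries; the swap repair in
# pair_into_cores resolves almost every junction clash, so retries are
# only needed when the final pair is left with a clashing junction
shuffle_into_cores <- function(tags, max_attempts = 50L) {
  for (attempt in seq_len(max_attempts)) {
    cores <- pair_into_cores(sample(tags))
    if (!is.null(cores)) return(cores)
  }
  stop("could not pair tags into anchor-free ditag cores; ",
       "a tag multiset this constrained cannot be concatemerized")
}

#' Realize a tag-count table as concatemer clone libraries
#'
#' Expands each library's tag multiset, shuffles it, pairs consecutive
#' tags into 34-bp ditag cores (second tag reverse-complemented), and
#' concatenates \code{tags_per_clone} cores per clone with CATG anchors
#' between and at both ends — the inverse of tag extraction. An
#' odd-sized library is padded by duplicating one random tag (recorded
#' in the \code{padding} attribute), so extraction round-trips to the
#' input table exactly up to that documented pad.
#'
#' @param table a \code{\link{tag_count_table}}.
#' @param tags_per_clone ditags per clone.
#' @param seed RNG seed for shuffling and padding.
#' @return list with \code{A}, \code{B}: concatemer data.frames
#'   (clone_id, sequence) writable by
#'   \code{\link{write_concatemer_fasta}}, and \code{padding}: per-library
#'   padded tag (NA when none).
#' @export
libraries_to_concatemers <- function(table, tags_per_clone = 8L, seed) {
  stopifnot(inherits(table, "tag_count_table"), tags_per_clone >= 1)
  if (missing(seed)) stop("libraries_to_concatemers requires an explicit seed")
  with_seed(seed, {
    one <- function(counts, prefix) {
      tags <- rep(table$tag, counts)
      if (length(tags) == 0) stop("empty library cannot be concatemerized")
      pad <- NA_character_
      if (length(tags) %% 2 == 1) {
        pad <- tags[sample.int(length(tags), 1)]
        tags <- c(tags, pad)
      }
      cores <- shuffle_into_cores(tags)
      groups <- split(cores, ceiling(seq_along(cores) / tags_per_clone))
      seqs <- vapply(groups, function(g) {
        paste0(ANCHOR, paste(g, collapse = ANCHOR), ANCHOR)
      }, character(1))
      list(records = data.frame(
             clone_id = sprintf("%s_clone_%04d", prefix, seq_along(seqs)),
             sequence = unname(seqs), stringsAsFactors = FALSE),
           pad = pad)
    }
    a <- one(table$count_A, "libA")
    b <- one(table$count_B, "libB")
    list(A = a$records, B = b$records,
         padding = c(A = a$pad, B = b$pad))
  })
}

#' Simulate qPCR wells and fluorescence curves with known truth
#'
#' Emulates a two-group (species A vs B) relative-quantification design:
#' one shared reference gene with a common base Ct in both groups, and
#' one target gene per entry whose group-A Ct is shifted by
#' \code{-log(true_ratio)/log(e)} cycles so that the efficiency-corrected
#' ratio Q_A/Q_B equals \code{true_ratio}. Gaussian cycle noise is added
#' to every well. Optional raw curves follow
#' \code{baseline + F0 * e^cycle} with multiplicative log-normal noise,
#' with F0 set so the curve crosses signal 1 at the well's Ct.
#'
#' @param genes data.frame with columns \code{name}, \code{true_ratio}
#'   (or a named numeric vector of ratios).
#' @param e amplification efficiency used for every well.
#' @param replicates replicates per group (>= 2).
#' @param noise_sd_ct SD of Gaussian Ct noise, in cycles.
#' @param seed mandatory RNG seed.
#' @param reference reference gene name.
#' @param base_ct_ref,base_ct_target noise-free base Ct values.
#' @param curves generate raw fluorescence curves as well.
#' @param n_cycles,curve_noise_sd,curve_baseline curve parameters
#'   (multiplicative noise SD on the log scale).
#' @return list of class \code{"qpcr_sim"}: \code{wells} (gene, group,
#'   replicate, ct, efficiency), \code{curves} (gene, group, replicate,
#'   cycle, signal; NULL unless requested), \code{truth}.
#' @export
simulate_qpcr <- function(genes, e = 2, replicates = 5L, noise_sd_ct = 0.2,
                          seed, reference = "GAPDH",
                          base_ct_ref = 18, base_ct_target = 24,
                          curves = FALSE, n_cycles = 40L,
                          curve_noise_sd = 0.01, curve_baseline = 0.05) {
  if (missing(seed)) stop("simulate_qpcr requires an explicit seed")
  stopifnot(replicates >= 2, e > 1, e <= 2, noise_sd_ct >= 0)
  if (!is.data.frame(genes)) {
    genes <- data.frame(name = names(genes), true_ratio = unname(genes),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "true_ratio") %in% names(genes)),
            all(genes$true_ratio > 0))
  with_seed(seed, {
    grid <- expand.grid(group = c("A", "B"), replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    make_wells <- function(name, base_ct) {
      data.frame(gene = name, group = grid$group, replicate = grid$replicate,
                 ct = base_ct + stats::rnorm(nrow(grid), 0, noise_sd_ct),
                 efficiency = e, stringsAsFactors = FALSE)
    }
    wells <- make_wells(reference, base_ct_ref)
    for (i in seq_len(nrow(genes))) {
      shift <- log(genes$true_ratio[i]) / log(e)
      w <- make_wells(genes$name[i], base_ct_target)
      w$ct <- w$ct - ifelse(w$group == "A", shift, 0)
      wells <- rbind(wells, w)
    }
    curve_df <- NULL
    if (curves) {
      rows <- lapply(seq_len(nrow(wells)), function(i) {
        f0 <- e^(-wells$ct[i])
        cyc <- seq_len(n_cycles)
        sig <- curve_baseline +
          f0 * e^cyc * exp(stats::rnorm(n_cycles, 0, curve_noise_sd))
        data.frame(gene = wells$gene[i], group = wells$group[i],
                   replicate = wells$replicate[i], cycle = cyc,
                   signal = sig, stringsAsFactors = FALSE)
      })
      curve_df <- do.call(rbind, rows)
    }
    structure(list(wells = wells, curves = curve_df, truth = genes),
              class = "qpcr_sim")
  })
}
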