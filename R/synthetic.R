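#' Default synthetic block layout (full study scale)
#'
#' The twelve fingerprint blocks at their full bit widths plus the 7-column
#' continuous descriptor block — the shape of the 450-compound DILIrank
#' feature set the generator emulates.
#'
#' @return data.frame with columns `block_id`, `kind`, `width`.
#' @export
default_block_specs <- function() {
  cat <- fingerprint_catalog()
  rbind(cat[, c("block_id", "kind", "width")],
        data.frame(block_id = "DESCRIPTORS", kind = "continuous",
                   width = 7L))
}

#' Compact synthetic block layout
#'
#' The same thirteen blocks with widths reduced roughly 16-fold
#' (proportionally to the full sizes, floor 16 bits). The planted signal
#' and Bayes accuracy are unaffected by width — extra columns are pure
#' noise — so analyses that only need the signal structure use this layout
#' to keep model fits fast.
#'
#' @return data.frame with columns `block_id`, `kind`, `width`.
#' @export
compact_block_specs <- function() {
  specs <- default_block_specs()
  fp <- specs$block_id != "DESCRIPTORS"
  specs$width[fp] <- pmax(16L, as.integer(specs$width[fp] %/% 16L))
  specs
}

#' Default planted class signal
#'
#' Two informative bits in each of ExtendedFP and KRFP (the two top-ranked
#' fingerprint families in the reference analysis), active with
#' probability `p1 = 0.70` in hepatotoxicants and `p0 = 0.30` in
#' non-hepatotoxicants. At the 182/268 class prior these four
#' conditionally independent bits give a Bayes-optimal accuracy of 0.8093
#' ([bayes_accuracy()]), i.e. a learnable but noisy signal comparable to
#' the real endpoint. Descriptors carry no signal by default, keeping the
#' Bayes rate analytic.
#'
#' @return named list of per-block signal specifications, each a list
#'   `n_informative`, `p1`, `p0`.
#' @export
default_signal <- function() {
  list(ExtendedFP = list(n_informative = 2L, p1 = 0.70, p0 = 0.30),
       KRFP = list(n_informative = 2L, p1 = 0.70, p0 = 0.30))
}

#' Configure the synthetic dataset generator
#'
#' @param n_compounds number of compounds (default 450).
#' @param positive_fraction fraction of hepatotoxicants (default 182/450).
#' @param block_specs block layout, a data.frame as returned by
#'   [default_block_specs()] or [compact_block_specs()].
#' @param signal named list: per-block planted signal. Binary blocks take
#'   `list(n_informative, p1, p0)` (Bernoulli activation per class); count
#'   blocks take `list(n_informative, mu1, mu0)` (Poisson means per
#'   class); the descriptor block takes `list(n_informative, shift)`
#'   (class-1 location shift in units of the descriptor's spread).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return an object of class `dili_generator_config`.
#' @export
generator_config <- function(n_compounds = 450,
                             positive_fraction = 182 / 450,
                             block_specs = default_block_specs(),
                             signal = default_signal(),
                             seed = 1L) {
  if (n_compounds < 2) abort("need at least 2 compounds")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    abort("positive_fraction must be in (0, 1)")
  if (any(block_specs$width < 1)) abort("block widths must be positive")
  for (id in names(signal)) {
    if (!id %in% block_specs$block_id)
      abort("signal refers to unknown block '%s'", id)
    sg <- signal[[id]]
    kind <- block_specs$kind[block_specs$block_id == id]
    if (sg$n_informative > block_specs$width[block_specs$block_id == id])
      abort("block '%s': more informative features than width", id)
    if (kind == "binary" &&
        (any(c(sg$p1, sg$p0) < 0) || any(c(sg$p1, sg$p0) > 1)))
      abort("block '%s': activation probabilities outside [0, 1]", id)
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 positive_fraction = positive_fraction,
                 block_specs = block_specs, signal = signal,
                 seed = as.integer(seed)),
            class = "dili_generator_config")
}

# per-descriptor base sampler parameters (location, spread, family);
# roughly the ranges of approved small-molecule drugs
descriptor_families <- function() {
  list(AlogP = list(family = "normal", mean = 2.2, sd = 1.6),
       MW = list(family = "lognormal", meanlog = log(330), sdlog = 0.35),
       nAR = list(family = "poisson", lambda = 1.4),
       nHBA = list(family = "poisson", lambda = 3.6),
       nHBD = list(family = "poisson", lambda = 1.6),
       nRTB = list(family = "poisson", lambda = 4.6),
       nR = list(family = "poisson", lambda = 2.6))
}

#' Generate a synthetic DILI-shaped dataset
#'
#' Draws labels at the configured class balance (the positive count is
#' exact, the order random), then per block: binary features Bernoulli,
#' count features Poisson, descriptors from per-column normal / log-normal
#' / Poisson families plausible for AlogP, MW and the count descriptors.
#' Informative features (the first `n_informative` columns of a signalled
#' block) use class-dependent rates; all remaining features use
#' class-independent background rates drawn once per feature.
#'
#' @param config a [generator_config()].
#' @return a `dili_dataset` with one feature block per configured block.
#' @export
generate_dili_data <- function(config) {
  stopifnot(inherits(config, "dili_generator_config"))
  n <- config$n_compounds
  n_pos <- as.integer(round_half_up(n * config$positive_fraction, 0))
  if (n_pos < 1 || n_pos >= n) abort("infeasible class sizes")
  set.seed(derive_seed(config$seed, "labels"))
  y <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  ids <- sprintf("CMP%04d", seq_len(n))
  blocks <- lapply(seq_len(nrow(config$block_specs)), function(bi) {
    id <- config$block_specs$block_id[bi]
    kind <- config$block_specs$kind[bi]
    width <- config$block_specs$width[bi]
    sg <- config$signal[[id]]
    set.seed(derive_seed(config$seed, "block", id))
    m <- if (kind == "continuous")
      generate_descriptors(n, y, sg)
    else
      generate_pattern_block(n, y, width, kind, sg)
    colnames(m) <- if (kind == "continuous") descriptor_names()
                   else paste0(id, "_", seq_len(width))
    feature_block(id, kind, m, compound_ids = ids)
  })
  labels <- stats::setNames(y, ids)
  assemble_dataset_quiet(blocks, labels)
}

# assemble without the dropped-compound message (nothing can drop here)
assemble_dataset_quiet <- function(blocks, labels) {
  suppressMessages(assemble_dataset(blocks, labels))
}

generate_pattern_block <- function(n, y, width, kind, sg) {
  k <- if (is.null(sg)) 0L else as.integer(sg$n_informative)
  m <- matrix(0, n, width)
  if (kind == "binary") {
    background <- stats::runif(width, 0.05, 0.5)
    for (j in seq_len(width)) {
      p <- if (j <= k) ifelse(y == 1, sg$p1, sg$p0) else background[j]
      m[, j] <- stats::rbinom(n, 1, p)
    }
  } else {
    background <- stats::runif(width, 0.1, 1.0)
    for (j in seq_len(width)) {
      lam <- if (j <= k) ifelse(y == 1, sg$mu1, sg$mu0) else background[j]
      m[, j] <- stats::rpois(n, lam)
    }
  }
  m
}

generate_descriptors <- function(n, y, sg) {
  fams <- descriptor_families()
  k <- if (is.null(sg)) 0L else as.integer(sg$n_informative)
  shift <- if (is.null(sg)) 0 else sg$shift
  m <- vapply(seq_along(fams), function(j) {
    f <- fams[[j]]
    s <- if (j <= k) shift else 0
    switch(f$family,
      normal = stats::rnorm(n, f$mean + s * f$sd * (y == 1), f$sd),
      lognormal = stats::rlnorm(n, f$meanlog + s * f$sdlog * (y == 1),
                                f$sdlog),
      poisson = stats::rpois(n, f$lambda * (1 + s * (y == 1))))
  }, numeric(n))
  m
}

#' Bayes-optimal accuracy of a generator configuration
#'
#' For configurations whose planted signal lives entirely in
#' conditionally independent Bernoulli (binary fingerprint) features, the
#' Bayes classifier thresholds the exact likelihood ratio over the
#' informative bits, and its accuracy is computed by enumeration over all
#' informative-bit patterns (Monte Carlo beyond 16 bits). With no signal
#' the Bayes rule is the majority class. Signals in count or descriptor
#' blocks have no closed form here and are an error.
#'
#' @param config a [generator_config()].
#' @param n_mc Monte Carlo sample size used when enumeration is infeasible.
#' @return the Bayes-optimal expected accuracy.
#' @export
bayes_accuracy <- function(config, n_mc = 2e5) {
  stopifnot(inherits(config, "dili_generator_config"))
  pi1 <- config$positive_fraction
  p1 <- numeric(0); p0 <- numeric(0)
  for (id in names(config$signal)) {
    kind <- config$block_specs$kind[config$block_specs$block_id == id]
    if (kind != "binary")
      abort("unsupported signal family: block '%s' is %s, not binary",
            id, kind)
    sg <- config$signal[[id]]
    if (sg$n_informative > 0) {
      p1 <- c(p1, rep(sg$p1, sg$n_informative))
      p0 <- c(p0, rep(sg$p0, sg$n_informative))
    }
  }
  k <- length(p1)
  if (k == 0) return(max(pi1, 1 - pi1))
  if (k <= 16) {
    patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
    # power form, not log form: p^x * (1-p)^(1-x) is exact for p in {0, 1}
    lik <- function(p) apply(patterns, 1, function(x)
      prod(p^x * (1 - p)^(1 - x)))
    sum(pmax(pi1 * lik(p1), (1 - pi1) * lik(p0)))
  } else {
    set.seed(derive_seed(config$seed, "bayes_mc"))
    y <- stats::rbinom(n_mc, 1, pi1)
    x <- matrix(stats::rbinom(n_mc * k, 1,
                              ifelse(rep(y, each = k) == 1, p1, p0)),
                ncol = k, byrow = TRUE)
    llr <- x %*% log(p1 / p0) + (1 - x) %*% log((1 - p1) / (1 - p0)) +
      log(pi1 / (1 - pi1))
    mean(as.integer(llr > 0) == y)
  }
}

#' Write a generated dataset to a directory of CSV tables
#'
#' One PaDEL-dialect CSV per block plus `labels.csv` — the on-disk layout
#' consumed by the command-line pipeline.
#'
#' @param dataset a `dili_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_dir <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in dataset$blocks)
    write_feature_table(b, file.path(dir, paste0(b$block_id, ".csv")))
  write_labels(dataset$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset_dir()]
#'
#' Block kinds are taken from [fingerprint_catalog()] for known ids,
#' `"continuous"` for `DESCRIPTORS`, and inferred from the values
#' otherwise (all 0/1: binary; all non-negative integers: count; else
#' continuous).
#'
#' @param dir dataset directory containing block CSVs and `labels.csv`.
#' @return a `dili_dataset`.
#' @export
read_dataset_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "labels.csv"]
  if (length(files) == 0) abort("no feature tables found in %s", dir)
  cat <- fingerprint_catalog()
  blocks <- lapply(files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    kind <- if (id %in% cat$block_id) cat$kind[cat$block_id == id]
            else if (id == "DESCRIPTORS") "continuous"
            else NA_character_
    if (is.na(kind)) {
      probe <- read_feature_table(f, id, "continuous")
      v <- probe$values
      kind <- if (all(v %in% c(0, 1))) "binary"
              else if (all(v >= 0 & v == floor(v))) "count"
              else "continuous"
      return(feature_block(id, kind, v, compound_ids = probe$compound_ids,
                           feature_names = probe$feature_names))
    }
    read_feature_table(f, id, kind)
  })
  labels_path <- file.path(dir, "labels.csv")
  if (!file.exists(labels_path)) abort("labels.csv not found in %s", dir)
  assemble_dataset(blocks, read_labels(labels_path))
}
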