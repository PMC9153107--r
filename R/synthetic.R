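#' Configuration for synthetic two-condition transcriptome cohorts
#'
#' Bundles the parameters of the cohort simulator. Defaults describe a
#' desk-scale multi-study-like cohort: 1000 genes of which 25 respond to
#' hypoxia by rising about 20 percentile points in the within-sample
#' expression ranking, 60 samples per condition, moderate per-sample noise,
#' 10% dropout and a 4-fold range of sequencing depths.
#'
#' @param n_genes Number of genes (>= 50).
#' @param n_samples_per_class Samples per condition (>= 5).
#' @param de_genes Number of hypoxia-responsive genes (< `n_genes`).
#' @param effect Mean upward shift, in rank-percentile points (0, 100], of
#'   responsive genes in hypoxic samples. Individual genes get shifts
#'   jittered by +/-25% around this mean.
#' @param noise_sd SD of per-sample log2-abundance jitter.
#' @param dropout_p Probability in \[0, 1) that a gene's value is zeroed in
#'   a given sample, applied before ranking so the tie-at-zero regime of
#'   real RNA-seq is exercised.
#' @param libsize_range Length-2 interval of multiplicative depth factors.
#'   Depth never changes within-sample ranks; it is simulated so raw values
#'   look like real libraries.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 1000L,
                             n_samples_per_class = 60L,
                             de_genes = 25L,
                             effect = 20,
                             noise_sd = 0.3,
                             dropout_p = 0.1,
                             libsize_range = c(0.5, 2),
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_class = as.integer(n_samples_per_class),
    de_genes = as.integer(de_genes),
    effect = as.numeric(effect),
    noise_sd = as.numeric(noise_sd),
    dropout_p = as.numeric(dropout_p),
    libsize_range = as.numeric(libsize_range),
    seed = as.integer(seed)
  )
  stopifnot(
    "n_genes must be >= 50" = cfg$n_genes >= 50L,
    "n_samples_per_class must be >= 5" = cfg$n_samples_per_class >= 5L,
    "de_genes must be positive and < n_genes" =
      cfg$de_genes >= 1L && cfg$de_genes < cfg$n_genes,
    "effect must be in (0, 100]" = cfg$effect > 0 && cfg$effect <= 100,
    "noise_sd must be non-negative" = cfg$noise_sd >= 0,
    "dropout_p must be in [0, 1)" = cfg$dropout_p >= 0 && cfg$dropout_p < 1,
    "libsize_range must be an increasing positive interval" =
      length(cfg$libsize_range) == 2L && all(cfg$libsize_range > 0) &&
        cfg$libsize_range[1] <= cfg$libsize_range[2]
  )
  structure(cfg, class = "synthetic_config")
}

# Run expr with a private RNG stream; the caller's RNG state is untouched.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# Draw gene baselines and calibrated per-gene shifts. The requested effect is
# expressed in percentile points; it is converted to a log2-abundance offset
# by mapping each responsive gene's baseline percentile to its target
# percentile through the empirical quantile function of the baselines.
simulate_gene_model <- function(cfg) {
  G <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(G))
  mu <- stats::rnorm(G, mean = 6, sd = 2)
  p0 <- 100 * (rank(mu, ties.method = "average") - 1) / (G - 1)
  # Responsive genes are drawn from those with headroom for at least half
  # the requested shift: hypoxia-inducible genes must be able to rise.
  pool <- which(100 - p0 >= cfg$effect / 2)
  if (length(pool) < cfg$de_genes) {
    stop("infeasible effect: only ", length(pool),
         " gene(s) have headroom >= effect/2 = ", cfg$effect / 2,
         " percentile points, but de_genes = ", cfg$de_genes, call. = FALSE)
  }
  de_idx <- sort(sample(pool, cfg$de_genes))
  if (cfg$effect >= 100) {
    # full effect means complete promotion: every responsive gene moves
    # strictly above the whole baseline ranking (no jitter at the limit)
    target <- rep(100, cfg$de_genes)
  } else {
    shift_pts <- cfg$effect * stats::runif(cfg$de_genes, 0.75, 1.25)
    # Dropout compresses the nonzero percentile range: a gene alive in a
    # sample sits at ~100*d + (1-d)*p and is alive with probability (1-d),
    # so a nominal baseline shift realizes as (1-d)^2 of itself on average.
    # Calibrate the target so the *realized* shift matches the request.
    shift_pts <- shift_pts / (1 - cfg$dropout_p)^2
    target <- pmin(100, p0[de_idx] + shift_pts)
  }
  mu_sorted <- sort(mu)
  target_mu <- mu_sorted[1 + round(target / 100 * (G - 1))]
  delta <- pmax(target_mu - mu[de_idx], 0) + 1e-6
  list(gene_ids = gene_ids, mu = mu, de_idx = de_idx, delta = delta)
}

# One expression matrix given per-sample labels (1 = hypoxic, 0 = normoxic).
simulate_expression <- function(cfg, model, hypoxic, sample_ids) {
  G <- cfg$n_genes
  n <- length(hypoxic)
  shift <- numeric(G)
  shift[model$de_idx] <- model$delta
  logab <- matrix(model$mu, nrow = G, ncol = n) +
    outer(shift, as.numeric(hypoxic)) +
    matrix(stats::rnorm(G * n, sd = cfg$noise_sd), nrow = G)
  vals <- 2^logab
  libsize <- stats::runif(n, cfg$libsize_range[1], cfg$libsize_range[2])
  vals <- sweep(vals, 2L, libsize, `*`)
  if (cfg$dropout_p > 0) {
    vals[matrix(stats::runif(G * n) < cfg$dropout_p, nrow = G)] <- 0
  }
  dimnames(vals) <- list(model$gene_ids, sample_ids)
  vals
}

new_labeled_dataset <- function(matrix, labels, truth, coords = NULL) {
  structure(
    list(matrix = matrix, labels = labels, truth = truth, coords = coords),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " samples (", sum(x$labels$label == "hypoxic"), " hypoxic, ",
      sum(x$labels$label == "normoxic"), " normoxic); ",
      length(x$truth), " responsive genes",
      if (!is.null(x$coords)) " [spatial]" else "", "\n", sep = "")
  invisible(x)
}

#' Simulate a labeled two-condition transcriptome cohort
#'
#' Draws per-gene baseline log2-abundances once, then generates normoxic and
#' hypoxic samples. In hypoxic samples a known subset of responsive genes is
#' shifted upward so its within-sample rank percentile rises on average by
#' about `effect` points; per-sample noise, dropout and library-size scaling
#' are applied on top. The identities of the responsive genes are returned as
#' ground truth so feature selection and classification can be scored.
#'
#' @param config A [synthetic_config()].
#' @param sample_seed Optional integer. The gene model (baselines, identity
#'   of responsive genes, calibrated shifts) is always drawn under
#'   `config$seed`; with `sample_seed` set, the samples themselves are drawn
#'   under this second seed instead. Two calls with the same config and
#'   different `sample_seed`s therefore yield independent cohorts with
#'   identical ground truth - the way to make matched train/test cohorts.
#' @return A `labeled_dataset`: `$matrix` (genes x samples expression),
#'   `$labels` (tibble with `sample_id`, `label` in normoxic/hypoxic),
#'   `$truth` (character IDs of responsive genes).
#' @examples
#' ds <- generate_cohort(synthetic_config(n_genes = 100, de_genes = 5,
#'                                        n_samples_per_class = 6, seed = 7))
#' ds
#' @export
generate_cohort <- function(config, sample_seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    model <- simulate_gene_model(config)
    gen <- function() {
      n_per <- config$n_samples_per_class
      hypoxic <- rep(c(0L, 1L), each = n_per)
      ids <- sprintf("s%03d", seq_len(2L * n_per))
      mat <- simulate_expression(config, model, hypoxic, ids)
      labels <- tibble::tibble(
        sample_id = ids,
        label = ifelse(hypoxic == 1L, "hypoxic", "normoxic")
      )
      new_labeled_dataset(mat, labels, model$gene_ids[model$de_idx])
    }
    if (is.null(sample_seed)) gen() else with_local_seed(sample_seed, gen())
  })
}

#' Simulate a spatial-transcriptomics grid with a hypoxic core
#'
#' Spots are laid out on a `n_rows` x `n_cols` grid; spots whose centers fall
#' within a disc are hypoxic, the rest normoxic. Each spot is one sample
#' generated exactly as in [generate_cohort()] (same gene model, noise,
#' dropout, depth variation), so an ensemble trained on a cohort from the
#' same config should recover the core.
#'
#' @param config A [synthetic_config()]; `n_samples_per_class` is ignored
#'   (the grid fixes the number of spots).
#' @param n_rows,n_cols Grid dimensions (spot coordinates are 1-based).
#' @param center Length-2 numeric, disc center in (row, col) units.
#' @param radius Disc radius in spot widths; must cover at least one spot
#'   and leave at least one spot outside.
#' @param sample_seed Optional second seed for the spot draws, as in
#'   [generate_cohort()]; the gene model stays tied to `config$seed`, so a
#'   classifier trained on a cohort from the same config applies directly.
#' @return A `labeled_dataset` whose `$coords` is a tibble with
#'   `sample_id`, `row`, `col`.
#' @export
generate_spatial <- function(config, n_rows = 10L, n_cols = 10L,
                             center = c((n_rows + 1) / 2, (n_cols + 1) / 2),
                             radius = 2.5, sample_seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            n_rows >= 2L, n_cols >= 2L, length(center) == 2L, radius > 0)
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  inside <- (grid$row - center[1])^2 + (grid$col - center[2])^2 <= radius^2
  if (!any(inside)) stop("empty core: no spot falls inside the disc", call. = FALSE)
  if (all(inside)) stop("empty exterior: the disc covers every spot", call. = FALSE)
  with_local_seed(config$seed, {
    model <- simulate_gene_model(config)
    gen <- function() {
      ids <- sprintf("spot_%02d_%02d", grid$row, grid$col)
      mat <- simulate_expression(config, model, as.integer(inside), ids)
      labels <- tibble::tibble(
        sample_id = ids,
        label = ifelse(inside, "hypoxic", "normoxic")
      )
      coords <- tibble::tibble(sample_id = ids, row = grid$row, col = grid$col)
      new_labeled_dataset(mat, labels, model$gene_ids[model$de_idx], coords)
    }
    if (is.null(sample_seed)) gen() else with_local_seed(sample_seed, gen())
  })
}
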