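# Seeded simulation of trees and correlated Brownian trait data, plus presets
# emulating the two sperm-heteromorphism comparative datasets.

#' Simulate a phylogeny for trait simulation
#'
#' `kind = "yule"` draws a pure-birth tree conditioned on `n_taxa` tips
#' (ultrametric) and rescales it to unit height, so simulated Brownian rates
#' are in per-tree-depth units and comparable across replicates.
#' `kind = "star"` returns the star phylogeny with every tip at distance 1
#' from the root, whose phylogenetic covariance is the identity — the
#' closed-form iid limit used heavily in tests.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param kind `"yule"` or `"star"`.
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param seed Optional integer; fully determines the yule draw and leaves
#'   the caller's RNG state untouched.
#' @return A `phylo` object with tips labelled `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, kind = c("yule", "star"), birth_rate = 1,
                          seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n_taxa) || n_taxa < 2 || n_taxa != round(n_taxa))
    stop_input("n_taxa must be an integer >= 2")
  n_taxa <- as.integer(n_taxa)
  if (kind == "star") {
    tree <- ape::stree(n_taxa, type = "star")
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    if (!is.numeric(birth_rate) || birth_rate <= 0)
      stop_input("birth_rate must be positive")
    tree <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
  }
  validate_phylogeny(tree)
  tree
}

#' Simulate correlated Brownian traits on a tree
#'
#' Draws one realisation of p traits evolving by correlated Brownian motion:
#' `X = 1 mu' + L_C Z U_R` with `L_C L_C' = C` (phylogenetic covariance of
#' `tree`), `U_R' U_R = R` (Cholesky factors) and `Z` an n x p standard
#' normal matrix, so that `vec(X) ~ N(vec(1 mu'), R %x% C)`. Rows are keyed
#' to tip labels.
#'
#' @param tree A `phylo` object.
#' @param R p x p positive-definite rate matrix (trait names taken from its
#'   dimnames, if any).
#' @param mu Numeric vector of length p of root states.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return n x p numeric matrix with species rownames.
#' @export
simulate_traits <- function(tree, R, mu, seed = NULL) {
  validate_phylogeny(tree)
  R <- as.matrix(R)
  if (!is_square_symmetric(R)) stop_input("R must be a symmetric matrix")
  p <- ncol(R)
  if (length(mu) != p) stop_input("mu has length %d, expected %d", length(mu), p)
  UR <- tryCatch(chol(R), error = function(e)
    stop_numeric("rate matrix is not positive definite"))
  C <- phylo_covariance(tree)
  LC <- chol_lower(C)
  n <- nrow(C)
  Z <- with_seed(seed, matrix(rnorm(n * p), n, p))
  X <- tcrossprod(rep(1, n), as.numeric(mu)) + LC %*% Z %*% UR
  dimnames(X) <- list(rownames(C),
                      if (!is.null(colnames(R))) colnames(R)
                      else names(mu) %||% paste0("trait", seq_len(p)))
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Preset parameterisations emulating the two comparative datasets: per-trait
# Brownian rates at the published observed-model scale and evolutionary
# correlations implied by the published observed covariances (plausible
# synthetic values, not the study's measured truth). Root states are log10
# lengths of biologically typical magnitudes, all in micrometres.
preset_params <- function(preset) {
  build_R <- function(rates, cors) {
    p <- length(rates)
    P <- diag(p)
    P[lower.tri(P)] <- cors
    P <- P + t(P) - diag(p)
    R <- diag(sqrt(rates)) %*% P %*% diag(sqrt(rates))
    dimnames(R) <- list(names(rates), names(rates))
    R
  }
  switch(preset,
    drosophila = {
      rates <- c(fertile_total = 0.99, nonfertile_total = 0.29,
                 wing = 0.03, seminal_receptacle = 1.09)
      # lower-tri order: (nf,f) (wing,f) (sr,f) (wing,nf) (sr,nf) (sr,wing)
      cors <- c(0.448, 0.522, 0.866, 0.214, 0.160, 0.332)
      list(n_taxa = 19L, R = build_R(rates, cors),
           mu = c(fertile_total = 2.54, nonfertile_total = 2.18,
                  wing = 3.30, seminal_receptacle = 2.60))
    },
    lepidoptera = {
      rates <- c(fertile_total = 0.053, nonfertile_total = 0.014,
                 forewing = 0.032)
      cors <- c(0.551, 0.340, 0.567)
      list(n_taxa = 12L, R = build_R(rates, cors),
           mu = c(fertile_total = 2.90, nonfertile_total = 2.60,
                  forewing = 4.00))
    },
    stop_input("unknown preset '%s' (use 'drosophila' or 'lepidoptera')", preset))
}

#' Synthetic dataset presets emulating the two study systems
#'
#' Generates a unit-height pure-birth tree and correlated Brownian traits
#' with the statistical structure of the two published sperm-heteromorphism
#' analyses: `"drosophila"` — 19 taxa, 4 traits (fertile and non-fertile
#' total sperm length, wing length, seminal receptacle length) with true
#' rates (0.99, 0.29, 0.03, 1.09); `"lepidoptera"` — 12 taxa, 3 traits
#' (fertile and non-fertile sperm length, forewing length) with true rates
#' (0.053, 0.014, 0.032). Traits are simulated on the log10 scale and
#' returned as linear lengths (micrometres) in `$traits`, so a downstream
#' log10 transform is exercised exactly as with real data. Evolutionary
#' correlations are plausible synthetic values implied by published observed
#' covariances. `missing_receptacle = TRUE` blanks the last trait for 4
#' random species (drosophila preset), emulating the incomplete
#' seminal-receptacle coverage that reduces a 19-species table to n = 15.
#'
#' @param preset `"drosophila"` or `"lepidoptera"`.
#' @param seed Integer seed; fully determines tree and traits.
#' @param missing_receptacle Logical; drop the final trait for 4 species.
#' @return List with `tree` (`phylo`), `traits` (data.frame of linear
#'   lengths with a `species` column), `X_log10` (the simulated log10
#'   matrix), `R_true`, `mu_true`.
#' @export
make_fixture <- function(preset = c("drosophila", "lepidoptera"), seed = 1,
                         missing_receptacle = FALSE) {
  if (is.character(preset) && length(preset) == 1 &&
      !preset %in% c("drosophila", "lepidoptera"))
    stop_input("unknown preset '%s' (use 'drosophila' or 'lepidoptera')", preset)
  preset <- match.arg(preset)
  par <- preset_params(preset)
  tree <- simulate_tree(par$n_taxa, kind = "yule", seed = seed)
  X <- simulate_traits(tree, par$R, par$mu, seed = seed + 1L)
  lin <- as.data.frame(10^X)
  if (missing_receptacle) {
    drop <- with_seed(seed + 2L, sample(nrow(lin), 4L))
    lin[drop, ncol(lin)] <- NA_real_
  }
  traits <- cbind(data.frame(species = rownames(X), stringsAsFactors = FALSE),
                  lin)
  rownames(traits) <- NULL
  list(tree = tree, traits = traits, X_log10 = X,
       R_true = par$R, mu_true = par$mu, preset = preset, seed = seed)
}

#' Write a fixture to newick + CSV files
#'
#' Serialises a [make_fixture()] result to `tree.nwk` and `traits.csv` in
#' `dir`, so synthetic data flow through exactly the same file interface as
#' real data.
#'
#' @param fixture A list from [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector with paths `tree` and `traits`.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tree_path <- file.path(dir, "tree.nwk")
  traits_path <- file.path(dir, "traits.csv")
  ape::write.tree(fixture$tree, file = tree_path)
  write.csv(fixture$traits, traits_path, row.names = FALSE, quote = FALSE)
  c(tree = tree_path, traits = traits_path)
}
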