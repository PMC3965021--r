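# Seeded generators for synthetic networks, expression data, gold standards
# and DEG queries with planted structure, so the whole pipeline is testable
# without any external download.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

default_gene_names <- function(n) sprintf("G%04d", seq_len(n))

resolve_modules <- function(modules, genes) {
  mods <- lapply(modules, function(m) {
    if (is.numeric(m)) genes[m] else toupper(as.character(m))
  })
  if (length(mods) > 1L && anyDuplicated(unlist(mods))) {
    stop("planted modules must be disjoint", call. = FALSE)
  }
  mods
}

#' Generate a random network with planted modules
#'
#' Gene pairs inside a module are linked with probability `p_in` and
#' weights drawn from `Normal(mean_in, sd_in)`; all remaining pairs with
#' probability `p_out` and `Normal(mean_out, sd_out)` weights. Weights are
#' truncated at zero (clamped to a small positive value), so edge
#' existence is governed by the probabilities alone. The same seed always
#' yields byte-identical output.
#'
#' @param n_genes Number of genes (named `G0001`, `G0002`, ...).
#' @param modules List of disjoint modules, each a vector of gene indices
#'   or names; may be empty for a pure Erdős–Rényi background.
#' @param p_in,p_out Within-module / background link probabilities,
#'   `0 <= p_out < p_in <= 1` when modules are planted.
#' @param mean_in,sd_in,mean_out,sd_out Weight distributions (defaults
#'   2.0/0.5 within-module, 0.5/0.5 background).
#' @param seed Integer seed, recorded in the output's `seed` attribute.
#' @return A [fl_network] tagged `"synthetic"`.
#' @export
make_network <- function(n_genes, modules = list(), p_in = 0.8, p_out = 0.05,
                         mean_in = 2.0, sd_in = 0.5,
                         mean_out = 0.5, sd_out = 0.5, seed = 1L) {
  stopifnot(n_genes >= 2L, p_out >= 0, p_in <= 1)
  if (length(modules)) stopifnot(p_out < p_in)
  genes <- default_gene_names(n_genes)
  mods <- resolve_modules(modules, genes)
  ut <- upper_idx(n_genes)
  in_module <- rep(FALSE, length(ut$i))
  for (m in mods) {
    idx <- match(m, genes)
    in_module <- in_module | (genes[ut$i] %in% m & genes[ut$j] %in% m)
  }
  with_seed(seed, {
    u <- stats::runif(length(ut$i))
    keep <- ifelse(in_module, u < p_in, u < p_out)
    w <- ifelse(in_module,
                stats::rnorm(length(ut$i), mean_in, sd_in),
                stats::rnorm(length(ut$i), mean_out, sd_out))
    w <- pmax(w, 1e-6)
    net <- fl_network(genes[ut$i][keep], genes[ut$j][keep], w[keep],
                      tag = "synthetic")
    attr(net, "seed") <- seed
    net
  })
}

#' Generate expression data with correlated planted modules
#'
#' Genes in a module share a latent per-condition factor:
#' `x = sqrt(rho) * f_module + sqrt(1 - rho) * noise`, giving an expected
#' pairwise within-module Pearson correlation of `rho`; background genes
#' are independent standard-normal noise.
#'
#' @param modules List of disjoint gene-name vectors (or index vectors
#'   into the first `n_genes` default names).
#' @param n_genes Total genes in the matrix (>= genes in modules).
#' @param n_conditions Number of conditions (>= 3).
#' @param rho Within-module correlation, `0 <= rho < 1`.
#' @param seed Integer seed.
#' @return Numeric gene-by-condition matrix.
#' @export
make_expression <- function(modules, n_genes, n_conditions = 100L, rho = 0.7,
                            seed = 1L) {
  stopifnot(rho >= 0, rho < 1, n_conditions >= 3L)
  genes <- default_gene_names(n_genes)
  mods <- resolve_modules(modules, genes)
  if (!all(unlist(mods) %in% genes)) stop("module gene outside the matrix", call. = FALSE)
  with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_conditions), nrow = n_genes,
                dimnames = list(genes, sprintf("C%03d", seq_len(n_conditions))))
    for (mod in mods) {
      f <- stats::rnorm(n_conditions)
      idx <- match(mod, genes)
      m[idx, ] <- sqrt(rho) * matrix(f, nrow = length(idx), ncol = n_conditions,
                                     byrow = TRUE) +
                  sqrt(1 - rho) * m[idx, , drop = FALSE]
    }
    m
  })
}

#' Gold standard from planted modules
#'
#' Treats the planted modules as annotation sets and delegates to
#' [gold_from_annotations()]: co-module pairs are positives, pairs of
#' module genes never sharing a module are negatives.
#'
#' @param modules Nonempty list of gene-name vectors.
#' @return A [gold_standard].
#' @export
make_gold <- function(modules) {
  if (!length(modules)) stop("need >= 1 module", call. = FALSE)
  nm <- names(modules)
  if (is.null(nm)) nm <- sprintf("M%02d", seq_along(modules))
  gold_from_annotations(gene_set_collection(stats::setNames(modules, nm)))
}

#' Generate a DEG query with a planted modulator hub
#'
#' Emulates a differential-expression query whose true modulator is a
#' network hub: the query is a random fraction of the hub's neighbors plus
#' noise genes drawn from the non-neighbors. The hub itself is excluded, so
#' the planted modulator — like real modulators that show no
#' transcriptional response — is not in the DEG list.
#'
#' @param net A [fl_network].
#' @param hub Hub gene; must be in the network and non-isolated.
#' @param fraction Fraction of the hub's neighbors to include, in (0, 1].
#' @param n_noise Number of random non-neighbor genes to add.
#' @param seed Integer seed.
#' @return Character vector of DEG identifiers.
#' @export
make_deg_query <- function(net, hub, fraction = 1, n_noise = 0L, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  hub <- toupper(hub)
  genes <- network_genes(net)
  if (!hub %in% genes) stop("hub '", hub, "' not in network", call. = FALSE)
  neighbors <- setdiff(unique(c(net$b[net$a == hub], net$a[net$b == hub])), hub)
  if (!length(neighbors)) stop("hub '", hub, "' is isolated", call. = FALSE)
  pool <- setdiff(genes, c(hub, neighbors))
  with_seed(seed, {
    n_take <- max(1L, ceiling(fraction * length(neighbors)))
    degs <- if (n_take >= length(neighbors)) neighbors else sample(neighbors, n_take)
    if (n_noise > 0L) degs <- c(degs, sample(pool, min(n_noise, length(pool))))
    sort(degs)
  })
}
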