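# Shared fixtures: tiny trees, toy communities, a brute-force UniFrac oracle,
# and memoized synthetic studies (generated once per test run).

tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# toy proportion vectors used across the recovery tests
toy_ref <- function() c(f1 = 0.50, f2 = 0.30, f3 = 0.199, f4 = 0.001)
toy_query <- function() c(f1 = 0.60, f2 = 0.395, f3 = 0, f4 = 0.005)

# Brute-force per-branch UniFrac: enumerates every edge's descendant tip set
# via phangorn::Descendants, independently of the package's postorder
# accumulation.
oracle_unifrac <- function(x, y, tree, weighted = FALSE, normalized = FALSE) {
  px_tot <- x / sum(x)
  py_tot <- y / sum(y)
  ntip <- length(tree$tip.label)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) child else
      phangorn::Descendants(tree, child, "tips")[[1]]
    labs <- tree$tip.label[tips]
    len <- tree$edge.length[e]
    px <- sum(px_tot[labs]); py <- sum(py_tot[labs])
    if (weighted) {
      num <- num + len * abs(px - py)
      den <- den + len * (px + py)
    } else {
      ax <- px > 0; ay <- py > 0
      if (xor(ax, ay)) num <- num + len
      if (ax || ay) den <- den + len
    }
  }
  if (weighted && !normalized) return(num)
  num / den
}

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_study <- function() memo("default_study",
                                 generate_study(synthetic_config(rng_seed = 1)))

default_analysis <- function() memo("default_analysis",
  run_study_analysis(default_study(), seed = 1))

# per-study OTU-level S2->mouse recovery and abundance captured over
# replicate studies at a given retention probability (seeds fixed 1..n)
replicate_recovery <- function(retention_p, n_rep = 20) {
  memo(sprintf("reprec_%g_%d", retention_p, n_rep), {
    t(vapply(seq_len(n_rep), function(s) {
      st <- generate_study(synthetic_config(retention_p = retention_p,
                                            rng_seed = s))
      rt <- recovery_table(st$counts, st$tax, st$manifest, "S2_vs_mouse",
                           ranks = "OTU")
      c(rec = mean(rt$recovery_pct), ab = mean(rt$abundance_captured_pct))
    }, c(rec = 0, ab = 0)))
  })
}

# small random community pair over a random tree, for property tests
random_unifrac_instance <- function(n_tips = 8) {
  tree <- ape::rtree(n_tips, br = stats::rexp)
  x <- stats::rpois(n_tips, 2)
  y <- stats::rpois(n_tips, 2)
  if (sum(x) == 0) x[sample.int(n_tips, 1)] <- 1
  if (sum(y) == 0) y[sample.int(n_tips, 1)] <- 1
  names(x) <- names(y) <- tree$tip.label
  list(tree = tree, x = x, y = y)
}
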