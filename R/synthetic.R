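# Synthetic-study generator: donor communities, straw-aliquot resamples,
# engrafted mouse communities, a random tree, synthetic lineages, manifests
# and serum phenotypes, with the statistical structure the analysis assumes.
#
# The defaults reproduce the study design: 8 donor subjects, 2 straw aliquots
# (S1, S2) and 3 recipient mice each, ~800 OTUs per donor, 60k reads per
# sample, heavy-tailed (log-normal) abundances, near-pure multinomial aliquot
# noise, and an engraftment stage that retains included OTUs at a baseline
# probability of 0.785 with losses concentrated in the 0.1-0.3% abundance
# band and phylum-biased abundance shifts (Bacteroidetes/Verrucomicrobia up,
# Firmicutes/Proteobacteria down).

SYNTH_PHYLA <- c(Firmicutes = 0.50, Bacteroidetes = 0.30,
                 Proteobacteria = 0.08, Actinobacteria = 0.05,
                 Tenericutes = 0.03, Verrucomicrobia = 0.02,
                 Fusobacteria = 0.02)

#' Configuration for a synthetic engraftment study
#'
#' @param n_subjects Number of donor subjects (default 8).
#' @param n_mice_per_subject Recipient mice per subject (default 3).
#' @param n_otus OTUs in the feature universe (default 800).
#' @param reads_per_sample Sequencing depth per sample (default 60000).
#' @param lognormal_sigma SD of the log-normal abundance draw; 2.0 gives the
#'   heavy-tailed profile where the top decile of OTUs holds most of the mass.
#' @param retention_p Baseline engraftment probability for OTUs passing the
#'   inclusion rule (default 0.785). The generator calibrates the retention
#'   curve per subject so the pipeline's measured OTU recovery is centered on
#'   this value.
#' @param dropout_abundance_exponent Slope of the logistic retention curve in
#'   log10 donor abundance; larger values concentrate losses in rarer taxa
#'   (default 0.6, placing typical losses in the 0.1-0.3% band).
#' @param dropout_pivot Abundance at which the retention curve is anchored
#'   (default 0.002, the middle of the loss band).
#' @param phylum_fold_changes Named multipliers applied to retained OTU
#'   abundance on engraftment (unlisted phyla get 1).
#' @param engraft_noise_sigma SD of the per-mouse log-normal abundance noise.
#' @param subject_otu_prevalence Probability that an OTU of the universe is
#'   present in a given donor (subject-specific presence masks).
#' @param aliquot_overdispersion Gamma overdispersion of aliquot sampling; 0
#'   (default) is pure multinomial, matching the observed near-total S1/S2
#'   concordance.
#' @param tau Inclusion threshold used for retention calibration (must match
#'   the analysis threshold; default 0.001).
#' @param tma_producer_fraction Fraction of OTUs designated TMA producers.
#' @param tmao_scale Serum TMAO per unit producer abundance.
#' @param tmao_noise_sd,choline_noise_sd Phenotype noise SDs.
#' @param choline_baseline Serum choline when no TMAO is produced.
#' @param choline_slope Drop in choline per unit TMAO.
#' @param rng_seed Root seed; every component derives its own sub-seed from it.
#' @return A validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 8, n_mice_per_subject = 3,
                             n_otus = 800, reads_per_sample = 60000,
                             lognormal_sigma = 2.0, retention_p = 0.785,
                             dropout_abundance_exponent = 0.6,
                             dropout_pivot = 0.002,
                             phylum_fold_changes = c(Bacteroidetes = 2,
                                                     Verrucomicrobia = 2,
                                                     Firmicutes = 0.5,
                                                     Proteobacteria = 0.5),
                             engraft_noise_sigma = 0.3,
                             subject_otu_prevalence = 0.8,
                             aliquot_overdispersion = 0,
                             tau = 0.001,
                             tma_producer_fraction = 0.05,
                             tmao_scale = 150, tmao_noise_sd = 2,
                             choline_baseline = 25, choline_slope = 0.4,
                             choline_noise_sd = 2,
                             rng_seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_mice_per_subject = n_mice_per_subject,
              n_otus = n_otus, reads_per_sample = reads_per_sample,
              lognormal_sigma = lognormal_sigma, retention_p = retention_p,
              dropout_abundance_exponent = dropout_abundance_exponent,
              dropout_pivot = dropout_pivot,
              phylum_fold_changes = phylum_fold_changes,
              engraft_noise_sigma = engraft_noise_sigma,
              subject_otu_prevalence = subject_otu_prevalence,
              aliquot_overdispersion = aliquot_overdispersion,
              tau = tau,
              tma_producer_fraction = tma_producer_fraction,
              tmao_scale = tmao_scale, tmao_noise_sd = tmao_noise_sd,
              choline_baseline = choline_baseline,
              choline_slope = choline_slope,
              choline_noise_sd = choline_noise_sd,
              rng_seed = rng_seed)
  stopifnot(cfg$n_subjects >= 1, cfg$n_mice_per_subject >= 1,
            cfg$n_otus >= 2, cfg$reads_per_sample >= 1,
            cfg$retention_p >= 0, cfg$retention_p <= 1,
            cfg$tau > 0, cfg$tau < 1,
            all(cfg$phylum_fold_changes > 0),
            cfg$subject_otu_prevalence > 0, cfg$subject_otu_prevalence <= 1)
  class(cfg) <- "synthetic_config"
  cfg
}

# deterministic sub-seed derivation from the root seed
.sub_seed <- function(seed, k) (abs(seed) %% 1000000L) * 1000L + k

#' Random bifurcating tree over synthetic OTUs
#'
#' Random-join topology with exponential(1) branch lengths and leaves
#' `OTU0001...`; deterministic given the seed.
#'
#' @param n_otus Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return Rooted [ape::phylo] tree.
#' @export
generate_tree <- function(n_otus, seed = 1) {
  if (n_otus < 2) stop("need at least 2 OTUs for a tree")
  set.seed(seed)
  ape::rtree(n_otus, rooted = TRUE, br = rexp,
             tip.label = sprintf("OTU%04d", seq_len(n_otus)))
}

#' Synthetic lineage table over the OTU universe
#'
#' Assigns every OTU to one of seven gut phyla (weighted toward Firmicutes
#' and Bacteroidetes) and to nested synthetic class/order/family/genus labels
#' within its phylum.
#'
#' @param n_otus Number of OTUs.
#' @param seed Integer seed.
#' @return Taxonomy data frame as produced by [read_taxonomy()].
#' @export
generate_taxonomy <- function(n_otus, seed = 1) {
  set.seed(seed)
  phylum <- sample(names(SYNTH_PHYLA), n_otus, TRUE, prob = SYNTH_PHYLA)
  # nested labels: 2 classes, 2 orders/class, 2 families/order, 3 genera/family
  cls <- sample.int(2, n_otus, TRUE)
  ord <- sample.int(2, n_otus, TRUE)
  fam <- sample.int(2, n_otus, TRUE)
  gen <- sample.int(3, n_otus, TRUE)
  data.frame(
    feature_id = sprintf("OTU%04d", seq_len(n_otus)),
    kingdom = "Bacteria",
    phylum = phylum,
    class = sprintf("%s_c%d", phylum, cls),
    order = sprintf("%s_c%d_o%d", phylum, cls, ord),
    family = sprintf("%s_c%d_o%d_f%d", phylum, cls, ord, fam),
    genus = sprintf("%s_c%d_o%d_f%d_g%d", phylum, cls, ord, fam, gen),
    stringsAsFactors = FALSE)
}

#' Donor community proportions for one subject
#'
#' Log-normal abundances over the OTU universe, masked by a subject-specific
#' Bernoulli presence pattern so that different donors share only part of
#' their OTUs, then normalized.
#'
#' @param config A [synthetic_config()].
#' @param subject_index Subject number (used only for reproducible labeling).
#' @param seed Integer seed.
#' @return Named proportion vector over `OTU0001...`, summing to 1.
#' @export
generate_donor_community <- function(config, subject_index = 1, seed = 1) {
  set.seed(seed)
  n <- config$n_otus
  repeat {
    mask <- rbinom(n, 1, config$subject_otu_prevalence)
    if (any(mask > 0)) break
  }
  a <- rlnorm(n, 0, config$lognormal_sigma) * mask
  a <- a / sum(a)
  names(a) <- sprintf("OTU%04d", seq_len(n))
  a
}

#' Sequence one aliquot of a donor community
#'
#' Multinomial read sampling from the donor proportions; with
#' `aliquot_overdispersion > 0` the proportions are first jittered by a
#' Dirichlet draw (gamma construction), giving overdispersed counts.
#'
#' @param donor Donor proportion vector.
#' @param reads Number of reads to draw.
#' @param seed Integer seed.
#' @param overdispersion Dirichlet scale (0 = pure multinomial).
#' @return Integer count vector with `sum == reads`.
#' @export
sample_aliquot <- function(donor, reads, seed = 1, overdispersion = 0) {
  stopifnot(reads >= 1)
  set.seed(seed)
  p <- donor
  if (overdispersion > 0) {
    pos <- donor > 0
    g <- numeric(length(donor))
    g[pos] <- rgamma(sum(pos), shape = donor[pos] / overdispersion)
    p <- if (sum(g) > 0) g / sum(g) else donor
  }
  counts <- rmultinom(1, reads, p)[, 1]
  names(counts) <- names(donor)
  counts
}

# Retention probabilities for engraftment. Logistic in log10 donor abundance
# with slope gamma, anchored at the pivot; the intercept is solved per donor
# so that the EXPECTED measured OTU recovery (which conditions on the 0.1%
# inclusion rule, making dropout failures among sub-threshold taxa invisible)
# equals retention_p. Inclusion probabilities use the binomial tail at the
# read-count threshold for S2 and the per-mouse log-normal bloom probability
# for retained taxa.
engraftment_retention_prob <- function(donor, fold, config) {
  rho <- config$retention_p
  pos <- donor > 0
  if (rho <= 0) return(numeric(length(donor)))
  if (rho >= 1) return(as.numeric(pos))
  gamma <- config$dropout_abundance_exponent
  sigma <- max(config$engraft_noise_sigma, 1e-6)
  reads <- config$reads_per_sample
  nmice <- config$n_mice_per_subject
  tau <- config$tau
  z <- ifelse(pos, log10(pmax(donor, 1e-12)) - log10(config$dropout_pivot), 0)
  cthr <- ceiling(reads * tau)
  q_s2 <- ifelse(pos, pbinom(cthr - 1L, reads, donor, lower.tail = FALSE), 0)
  p_pres <- ifelse(pos, 1 - dbinom(0, reads, donor), 0)
  Z <- sum(donor * plogis(qlogis(rho) + gamma * z) * fold)
  eta0 <- qlogis(rho)
  for (it in 1:3) {
    expected_rec <- function(e0) {
      p <- plogis(e0 + gamma * z)
      w <- donor * fold / max(Z, 1e-300)
      q_m1 <- ifelse(pos, plnorm(tau / pmax(w, 1e-300), 0, sigma,
                                 lower.tail = FALSE), 0)
      q_m <- 1 - (1 - q_m1)^nmice
      det <- ifelse(pos, 1 - exp(-nmice * reads * w * exp(sigma^2 / 2)), 0)
      q_inc1 <- q_s2 + (1 - q_s2) * q_m
      num <- sum(p_pres * p * q_inc1 * det)
      den <- sum(p_pres * (p * q_inc1 + (1 - p) * q_s2))
      num / max(den, 1e-300)
    }
    lo <- expected_rec(-15) - rho
    hi <- expected_rec(15) - rho
    if (lo >= 0) { eta0 <- -15; break }
    if (hi <= 0) { eta0 <- 15; break }
    eta0 <- uniroot(function(e) expected_rec(e) - rho, c(-15, 15))$root
    Z <- sum(donor * plogis(eta0 + gamma * z) * fold)
  }
  ifelse(pos, plogis(eta0 + gamma * z), 0)
}

#' Simulate engraftment of a donor community into germ-free mice
#'
#' Each donor OTU is retained once per subject (shared by all of the
#' subject's mice, modeling host/diet selection on taxa) with an
#' abundance-dependent probability centered on `retention_p`; retained OTU
#' abundances are multiplied by their phylum's fold change and per-mouse
#' log-normal noise, then renormalized.
#'
#' @param donor Donor proportion vector (named by OTU).
#' @param tax Taxonomy data frame covering the OTUs.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `props` (OTU x mouse proportion matrix), `retained`
#'   (logical), and `retention_prob`.
#' @export
simulate_engraftment <- function(donor, tax, config, seed = 1) {
  idx <- match(names(donor), tax$feature_id)
  if (anyNA(idx)) stop("donor OTU(s) missing from taxonomy")
  fold <- config$phylum_fold_changes[tax$phylum[idx]]
  fold[is.na(fold)] <- 1
  fold <- unname(fold)
  p <- engraftment_retention_prob(donor, fold, config)
  set.seed(seed)
  keep <- rbinom(length(donor), 1, p)
  props <- matrix(0, length(donor), config$n_mice_per_subject,
                  dimnames = list(names(donor), NULL))
  for (m in seq_len(config$n_mice_per_subject)) {
    noise <- if (config$engraft_noise_sigma > 0) {
      rlnorm(length(donor), 0, config$engraft_noise_sigma)
    } else 1
    w <- donor * keep * fold * noise
    if (sum(w) > 0) w <- w / sum(w)
    props[, m] <- w
  }
  list(props = props, retained = keep == 1, retention_prob = p)
}

#' Simulate serum TMAO and choline phenotypes
#'
#' Each subject's latent TMA-production capacity is the summed donor
#' abundance of the designated producer OTUs; each of its mice gets
#' `tmao = tmao_scale * capacity + noise` and
#' `choline = choline_baseline - choline_slope * tmao + noise`, truncated at
#' zero. A subject without producer taxa yields near-baseline-noise TMAO and
#' maximal choline.
#'
#' @param capacity Named numeric vector of per-subject producer abundance.
#' @param manifest Sample manifest (mouse rows receive phenotypes).
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Metabolite data frame (`sample_id`, `tmao`, `choline`) over mouse
#'   samples.
#' @export
simulate_phenotypes <- function(capacity, manifest, config, seed = 1) {
  set.seed(seed)
  mice <- manifest[manifest$role == "mouse", , drop = FALSE]
  cap <- capacity[mice$subject_id]
  if (anyNA(cap)) stop("capacity missing for subject(s): ",
                       paste(unique(mice$subject_id[is.na(cap)]), collapse = ", "))
  tmao <- pmax(0, config$tmao_scale * cap +
                 rnorm(nrow(mice), 0, config$tmao_noise_sd))
  choline <- pmax(0, config$choline_baseline - config$choline_slope * tmao +
                    rnorm(nrow(mice), 0, config$choline_noise_sd))
  data.frame(sample_id = mice$sample_id, tmao = as.numeric(tmao),
             choline = as.numeric(choline), stringsAsFactors = FALSE)
}

#' Generate a complete synthetic engraftment study
#'
#' Produces the full bundle the analysis consumes: count table over
#' `n_subjects x (S1, S2, mice)` samples, taxonomy, rooted tree, manifest,
#' serum metabolites, plus the latent truth (donor proportions, retention).
#' Fully reproducible from the config's root seed.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_study` with elements `counts`, `tax`,
#'   `tree`, `manifest`, `metabolites`, `donors` (OTU x subject truth),
#'   `retained` (OTU x subject logical), `config`.
#' @export
generate_study <- function(config = synthetic_config()) {
  seed <- config$rng_seed
  n <- config$n_otus
  tree <- generate_tree(n, .sub_seed(seed, 1))
  tax <- generate_taxonomy(n, .sub_seed(seed, 2))
  set.seed(.sub_seed(seed, 3))
  producers <- sample.int(n, max(1, round(config$tma_producer_fraction * n)))
  otus <- sprintf("OTU%04d", seq_len(n))
  samples <- list(); manifest <- list(); donors <- list(); retained <- list()
  capacity <- numeric(0)
  for (s in seq_len(config$n_subjects)) {
    sid <- paste0("sub", s)
    donor <- generate_donor_community(config, s, .sub_seed(seed, 10 + s))
    donors[[sid]] <- donor
    capacity[sid] <- sum(donor[producers])
    s1 <- sample_aliquot(donor, config$reads_per_sample,
                         .sub_seed(seed, 100 + s),
                         config$aliquot_overdispersion)
    s2 <- sample_aliquot(donor, config$reads_per_sample,
                         .sub_seed(seed, 200 + s),
                         config$aliquot_overdispersion)
    eng <- simulate_engraftment(donor, tax, config, .sub_seed(seed, 300 + s))
    retained[[sid]] <- eng$retained
    samples[[paste0(sid, "_S1")]] <- s1
    samples[[paste0(sid, "_S2")]] <- s2
    manifest[[length(manifest) + 1]] <- data.frame(
      sample_id = paste0(sid, c("_S1", "_S2")), subject_id = sid,
      role = c("S1", "S2"), replicate = 1L, stringsAsFactors = FALSE)
    for (m in seq_len(config$n_mice_per_subject)) {
      id <- sprintf("%s_M%d", sid, m)
      samples[[id]] <- sample_aliquot(eng$props[, m], config$reads_per_sample,
                                      .sub_seed(seed, 400 + s * 10 + m))
      manifest[[length(manifest) + 1]] <- data.frame(
        sample_id = id, subject_id = sid, role = "mouse",
        replicate = as.integer(m), stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, samples)
  rownames(counts) <- otus
  storage.mode(counts) <- "integer"
  manifest <- do.call(rbind, manifest)
  metab <- simulate_phenotypes(capacity, manifest, config, .sub_seed(seed, 5))
  study <- list(counts = counts, tax = tax, tree = tree, manifest = manifest,
                metabolites = metab,
                donors = do.call(cbind, donors),
                retained = do.call(cbind, retained),
                producers = otus[sort(producers)],
                config = config)
  class(study) <- "synthetic_study"
  study
}

#' Write a synthetic study bundle to a directory
#'
#' Emits `counts.tsv`, `taxonomy.tsv`, `tree.nwk`, `manifest.tsv`,
#' `metabolites.tsv` in the package's file dialects.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(study$counts, file.path(dir, "counts.tsv"))
  write_taxonomy(study$tax, file.path(dir, "taxonomy.tsv"))
  write_tree(study$tree, file.path(dir, "tree.nwk"))
  write_manifest(study$manifest, file.path(dir, "manifest.tsv"))
  write_metabolites(study$metabolites, file.path(dir, "metabolites.tsv"))
  invisible(dir)
}

#' Read a study bundle written by [write_study()]
#'
#' @param dir Directory containing the bundle.
#' @return List with `counts`, `tax`, `tree`, `manifest`, `metabolites`.
#' @export
read_study <- function(dir) {
  counts <- read_count_table(file.path(dir, "counts.tsv"))
  list(counts = counts,
       tax = read_taxonomy(file.path(dir, "taxonomy.tsv")),
       tree = read_tree(file.path(dir, "tree.nwk")),
       manifest = read_manifest(file.path(dir, "manifest.tsv"), counts),
       metabolites = read_metabolites(file.path(dir, "metabolites.tsv")))
}
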