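#' Describe a factorial community design for simulation
#'
#' Defines a Dirichlet-multinomial community simulation shaped like a
#' multi-species gut survey: host species crossed with seasons and gut
#' parts, a fixed number of samples per cell, and multiplicative
#' log-abundance shifts applied to a fraction of taxa for each factor
#' level. All samples share one Dirichlet-drawn base composition; group
#' structure enters only through the shift vectors, so setting every
#' effect to 0 yields a fully exchangeable null design under which
#' permutation tests should reject at their nominal rate.
#'
#' Per-sample sequencing depths are log-normal (default median 30,000
#' reads) so that rarefaction to 17,248 reads drops a small minority of
#' samples, mimicking uneven real-world depths.
#'
#' @param species character vector of host species labels (default: seven
#'   lake fish).
#' @param seasons,gut_parts factor levels for the other two design axes.
#' @param samples_per_cell samples in each species x season x gut-part cell.
#' @param n_asvs number of taxa simulated.
#' @param base_concentration Dirichlet concentration of the shared base
#'   composition (small values give realistic uneven communities).
#' @param species_effect,season_effect,gutpart_effect absolute log-scale
#'   shift applied to affected taxa for each level of the factor
#'   (0 disables the factor).
#' @param effect_fraction fraction of taxa shifted per factor level.
#' @param sample_noise_sd per-sample log-abundance noise SD.
#' @param depth_meanlog,depth_sdlog log-normal depth parameters.
#' @param seed integer RNG seed, recorded in the truth record.
#' @return a validated design list of class `"community_design"`.
#' @export
community_design <- function(species = c("H. molitrix", "A. nobilis",
                                         "C. auratus", "C. alburnus",
                                         "C. brachygnathus", "C. carpio",
                                         "C. ectenes taihuensis"),
                             seasons = c("spring", "summer", "autumn",
                                         "winter"),
                             gut_parts = c("foregut", "hindgut"),
                             samples_per_cell = 4L,
                             n_asvs = 300L,
                             base_concentration = 0.3,
                             species_effect = 1,
                             season_effect = 1,
                             gutpart_effect = 1,
                             effect_fraction = 0.2,
                             sample_noise_sd = 0.3,
                             depth_meanlog = log(30000),
                             depth_sdlog = 0.35,
                             seed = 1L) {
  d <- list(species = species, seasons = seasons, gut_parts = gut_parts,
            samples_per_cell = as.integer(samples_per_cell),
            n_asvs = as.integer(n_asvs),
            base_concentration = base_concentration,
            species_effect = species_effect,
            season_effect = season_effect,
            gutpart_effect = gutpart_effect,
            effect_fraction = effect_fraction,
            sample_noise_sd = sample_noise_sd,
            depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
            seed = as.integer(seed))
  stopifnot(length(d$species) >= 1, length(d$seasons) >= 1,
            length(d$gut_parts) >= 1, d$samples_per_cell >= 1,
            d$n_asvs >= 2, d$base_concentration > 0,
            d$species_effect >= 0, d$season_effect >= 0,
            d$gutpart_effect >= 0,
            d$effect_fraction >= 0, d$effect_fraction <= 1,
            d$sample_noise_sd >= 0, d$depth_sdlog >= 0)
  class(d) <- "community_design"
  d
}

# one signed shift vector per factor level; empty when effect == 0
shift_matrix <- function(levels_, n_asvs, effect, fraction) {
  m <- matrix(0, nrow = n_asvs, ncol = length(levels_),
              dimnames = list(NULL, levels_))
  affected <- vector("list", length(levels_))
  names(affected) <- levels_
  n_hit <- floor(fraction * n_asvs)
  if (effect > 0 && n_hit > 0) {
    for (lv in levels_) {
      idx <- sample.int(n_asvs, n_hit)
      sgn <- sample(c(-1, 1), n_hit, replace = TRUE)
      m[idx, lv] <- effect * sgn
      affected[[lv]] <- data.frame(taxon = idx, shift = effect * sgn)
    }
  }
  list(shifts = m, affected = affected)
}

#' Simulate a factorial ASV community with known ground truth
#'
#' Draws one base composition from a Dirichlet distribution, applies the
#' design's per-level log-abundance shifts and per-sample noise, converts
#' to probabilities by softmax, draws a log-normal depth, and samples
#' counts from a multinomial. Fixed seeds give bit-identical output.
#'
#' @param design a [community_design()].
#' @return list with elements `table` (an [asv_table()]), `metadata`
#'   (a [sample_metadata()]), and `truth` (base weights, every shifted
#'   taxon with its signed effect, depths, seed).
#' @export
simulate_community <- function(design) {
  stopifnot(inherits(design, "community_design"))
  set.seed(design$seed)
  n <- design$n_asvs
  base_w <- rdirichlet1(rep(design$base_concentration, n))
  log_base <- log(base_w)
  sp <- shift_matrix(design$species, n, design$species_effect,
                     design$effect_fraction)
  se <- shift_matrix(design$seasons, n, design$season_effect,
                     design$effect_fraction)
  gp <- shift_matrix(design$gut_parts, n, design$gutpart_effect,
                     design$effect_fraction)

  cells <- expand.grid(gut_part = design$gut_parts,
                       season = design$seasons,
                       species = design$species,
                       stringsAsFactors = FALSE)
  n_samples <- nrow(cells) * design$samples_per_cell
  md <- cells[rep(seq_len(nrow(cells)), each = design$samples_per_cell),
              c("species", "season", "gut_part"), drop = FALSE]
  md$sample_id <- sprintf("S%04d", seq_len(n_samples))
  md <- md[, c("sample_id", "species", "season", "gut_part")]

  counts <- matrix(0L, nrow = n, ncol = n_samples,
                   dimnames = list(sprintf("asv%04d", seq_len(n)),
                                   md$sample_id))
  depths <- integer(n_samples)
  for (i in seq_len(n_samples)) {
    eta <- log_base + sp$shifts[, md$species[i]] +
      se$shifts[, md$season[i]] + gp$shifts[, md$gut_part[i]] +
      stats::rnorm(n, 0, design$sample_noise_sd)
    depths[i] <- max(1L, round(stats::rlnorm(1, design$depth_meanlog,
                                             design$depth_sdlog)))
    counts[, i] <- stats::rmultinom(1, depths[i], softmax(eta))[, 1L]
  }
  list(table = asv_table(counts),
       metadata = sample_metadata(md),
       truth = list(seed = design$seed, design = design,
                    base_weights = base_w,
                    species_affected = sp$affected,
                    season_affected = se$affected,
                    gutpart_affected = gp$affected,
                    depths = stats::setNames(depths, md$sample_id)))
}

#' Generate a uniform taxonomy for simulated ASVs
#'
#' Assigns each simulated ASV a synthetic lineage by cycling taxa through
#' `n_phyla` phylum labels and `n_genera` genus labels; deeper ranks reuse
#' the genus label and a fraction are marked `"unclassified"` at genus
#' level to exercise the pseudo-taxon path.
#'
#' @param asv_ids character vector of ASV ids.
#' @param n_phyla,n_genera number of distinct labels per rank.
#' @param unclassified_fraction fraction of ASVs left unclassified at
#'   genus and species rank.
#' @param seed RNG seed.
#' @return a [taxonomy_table()].
#' @export
simulate_taxonomy <- function(asv_ids, n_phyla = 6L, n_genera = 30L,
                              unclassified_fraction = 0.2, seed = 1L) {
  set.seed(seed)
  n <- length(asv_ids)
  phylum <- paste0("Phylum", 1L + (seq_len(n) %% n_phyla))
  genus <- paste0("Genus", 1L + (seq_len(n) %% n_genera))
  unk <- stats::runif(n) < unclassified_fraction
  genus[unk] <- "unclassified"
  df <- data.frame(asv_id = asv_ids, domain = "Bacteria", phylum = phylum,
                   class = paste0(phylum, "_c"),
                   order = paste0(phylum, "_o"),
                   family = paste0(phylum, "_f"),
                   genus = genus,
                   species = ifelse(unk, "unclassified",
                                    paste0(genus, "_sp")),
                   stringsAsFactors = FALSE)
  taxonomy_table(df)
}

#' Describe a planted correlated-block design
#'
#' Taxa are organised into latent-factor blocks: every taxon in a block
#' loads on that block's per-sample Gaussian factor with weight `rho`
#' (half the block with positive sign, half negative), so within-block
#' abundances are rank-correlated with magnitude about `rho^2` on the
#' latent scale while between-block taxa are (near) independent. The
#' alternating signs keep each block's total abundance roughly constant,
#' which cancels the spurious cross-block correlations that compositional
#' closure of the softmax-multinomial observation layer would otherwise
#' induce. Optional hub taxa load equally on `hub_block_count` blocks,
#' emulating connector nodes; `factor_cor` sets a common correlation
#' between block factors, which raises the attainable hub-to-block
#' correlation (the ceiling is \eqn{\rho^2\sqrt{(1+(k-1)c)/k}} for a hub
#' on k blocks) while keeping between-block taxon correlations at the
#' modest level \eqn{\rho^2 c}.
#'
#' @param n_blocks number of blocks.
#' @param block_size taxa per block (scalar or per-block vector, each
#'   \eqn{\ge} 3).
#' @param rho latent loading in (0, 1); higher = tighter blocks.
#' @param n_hubs number of cross-block hub taxa.
#' @param hub_block_count how many blocks each hub loads on.
#' @param factor_cor correlation between block factors in [0, 1).
#' @param n_samples number of samples.
#' @param n_noise number of unstructured background taxa.
#' @param depth multinomial reads per sample.
#' @param latent_scale multiplier from latent z to log-abundance.
#' @param seed RNG seed.
#' @return design list of class `"planted_network_design"`.
#' @export
planted_network_design <- function(n_blocks = 3L, block_size = 10L,
                                   rho = 0.9, n_hubs = 0L,
                                   hub_block_count = 2L,
                                   factor_cor = 0,
                                   n_samples = 60L, n_noise = 0L,
                                   depth = 20000L, latent_scale = 1.5,
                                   seed = 1L) {
  sizes <- rep_len(as.integer(block_size), n_blocks)
  d <- list(n_blocks = as.integer(n_blocks), block_sizes = sizes,
            rho = rho, n_hubs = as.integer(n_hubs),
            hub_block_count = as.integer(hub_block_count),
            factor_cor = factor_cor,
            n_samples = as.integer(n_samples),
            n_noise = as.integer(n_noise), depth = as.integer(depth),
            latent_scale = latent_scale, seed = as.integer(seed))
  stopifnot(d$n_blocks >= 1, all(d$block_sizes >= 3),
            d$rho >= 0, d$rho < 1,
            d$n_hubs >= 0, d$hub_block_count >= 1,
            d$hub_block_count <= d$n_blocks,
            d$factor_cor >= 0, d$factor_cor < 1,
            d$n_samples >= 4, d$n_noise >= 0, d$depth >= 100,
            d$latent_scale > 0)
  class(d) <- "planted_network_design"
  d
}

#' Simulate counts with planted correlated ASV blocks
#'
#' @param design a [planted_network_design()].
#' @return list with `table` (an [asv_table()]) and `truth`, a data.frame
#'   with one row per taxon: `asv_id`, `role` (`"block"`, `"hub"`,
#'   `"noise"`), `block` (block id or `NA`), and `hub_blocks`
#'   (comma-separated block ids for hubs).
#' @export
simulate_correlated_counts <- function(design) {
  stopifnot(inherits(design, "planted_network_design"))
  set.seed(design$seed)
  nb <- design$n_blocks
  sizes <- design$block_sizes
  n_block_taxa <- sum(sizes)
  n <- n_block_taxa + design$n_hubs + design$n_noise
  block_of <- rep(seq_len(nb), sizes)
  hub_sets <- lapply(seq_len(design$n_hubs), function(i)
    sort(sample.int(nb, design$hub_block_count)))

  role <- c(rep("block", n_block_taxa), rep("hub", design$n_hubs),
            rep("noise", design$n_noise))
  ids <- sprintf("asv%03d", seq_len(n))
  rho <- design$rho
  resid_sd <- sqrt(1 - rho^2)
  # alternating loading signs within each block cancel compositional
  # closure of the softmax layer
  sign_of <- unlist(lapply(sizes, function(sz)
    rep_len(c(1, -1), sz)), use.names = FALSE)
  cc <- design$factor_cor
  sigma_f <- matrix(cc, nb, nb); diag(sigma_f) <- 1
  chol_f <- chol(sigma_f)
  hub_norm <- vapply(hub_sets, function(bs) {
    k <- length(bs)
    sqrt(k + k * (k - 1) * cc)
  }, 0)

  counts <- matrix(0L, nrow = n, ncol = design$n_samples,
                   dimnames = list(ids,
                                   sprintf("S%03d",
                                           seq_len(design$n_samples))))
  for (s in seq_len(design$n_samples)) {
    f <- drop(crossprod(chol_f, stats::rnorm(nb)))
    z <- stats::rnorm(n)            # unit-variance residuals
    z[role == "block"] <- sign_of * rho * f[block_of] +
      resid_sd * z[role == "block"]
    if (design$n_hubs > 0) {
      # hubs track the communal block factors exactly (unit loading, no
      # idiosyncratic residual): they are planted connectors, and this
      # keeps their correlation to every member block comfortably above
      # what thresholding removes
      hub_idx <- which(role == "hub")
      for (h in seq_along(hub_idx)) {
        bs <- hub_sets[[h]]
        z[hub_idx[h]] <- sum(f[bs]) / hub_norm[h]
      }
    }
    counts[, s] <- stats::rmultinom(1, design$depth,
                                    softmax(design$latent_scale * z))[, 1L]
  }
  truth <- data.frame(
    asv_id = ids, role = role,
    block = c(block_of, rep(NA_integer_, design$n_hubs + design$n_noise)),
    loading_sign = c(sign_of, rep(NA_real_,
                                  design$n_hubs + design$n_noise)),
    hub_blocks = c(rep(NA_character_, n_block_taxa),
                   vapply(hub_sets, paste, "", collapse = ","),
                   rep(NA_character_, design$n_noise)),
    stringsAsFactors = FALSE)
  list(table = asv_table(counts), truth = truth,
       seed = design$seed, design = design)
}
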