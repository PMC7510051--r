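# Synthetic regional soil-fungal survey generator. Produces an environment
# table, an OTU count table with known per-OTU Gaussian pH niches and
# host-tree links, and injected artifacts (mold-spoiled samples, low-depth
# samples, negative/positive controls), together with the ground truth
# needed for parameter-recovery tests. Everything is seeded and
# reproducible.

tree_genera <- function() {
  c("Picea", "Pinus", "Betula", "Quercus", "Salix", "Alnus", "Corylus",
    "Tilia", "Acer", "Fraxinus")
}

ecm_tree_genera <- function() {
  c("Picea", "Pinus", "Betula", "Quercus", "Salix", "Alnus", "Corylus",
    "Tilia")
}

habitat_types <- function() {
  c("forest", "woodland", "park", "grassland", "cropland", "bog", "ruin",
    "energy plantation", "wasteland", "alley")
}

#' Synthetic genus-level traits lookup table
#'
#' A small, entirely synthetic traits table in the format expected by
#' [annotate_function()]: one row per genus (species rows override
#' multi-lifestyle genera), mapping to guild, ectomycorrhizal lineage,
#' exploration type and mold group. It mimics the structure of a real
#' fungal traits database but covers only the genera that the synthetic
#' survey generator emits; it is not a reference resource.
#'
#' @return Tibble with columns `genus`, `species`, `multi_lifestyle`,
#'   `guild`, `ecm_lineage`, `exploration_type`, `mold_group`.
#' @export
synthetic_traits <- function() {
  g <- function(genus, guild, lineage = NA, expl = NA, mold = NA,
                multi = FALSE, species = NA) {
    tibble(genus = genus, species = as.character(species),
           multi_lifestyle = multi, guild = guild,
           ecm_lineage = as.character(lineage),
           exploration_type = as.character(expl),
           mold_group = as.character(mold))
  }
  dplyr::bind_rows(
    g("Russula", "EcM", "/russula-lactarius", "contact"),
    g("Lactarius", "EcM", "/russula-lactarius", "contact"),
    g("Inocybe", "EcM", "/inocybe", "short-distance-delicate"),
    g("Cortinarius", "EcM", "/cortinarius", "medium-distance-fringe"),
    g("Tomentella", "EcM", "/tomentella-thelephora", "medium-distance-smooth"),
    g("Amanita", "EcM", "/amanita", "medium-distance-smooth"),
    g("Suillus", "EcM", "/suillus-rhizopogon", "long-distance"),
    g("Hebeloma", "EcM", "/hebeloma-alnicola", "short-distance-coarse"),
    g("Piloderma", "EcM", "/piloderma", "medium-distance-fringe"),
    g("Hyaloscypha", "EcM", "/meliniomyces", "short-distance-delicate"),
    g("Tuber", "EcM", "/tuber-helvella", "short-distance-delicate"),
    g("Mortierella", "soil saprotroph", mold = "Mortierellales"),
    g("Umbelopsis", "soil saprotroph", mold = "Umbelopsidales"),
    g("Mucor", "soil saprotroph", mold = "Mucorales"),
    g("Penicillium", "soil saprotroph", mold = "Pezizomycotina_mold"),
    g("Aspergillus", "soil saprotroph", mold = "Pezizomycotina_mold"),
    g("Trichoderma", "mycoparasite"),
    g("Mycena", "litter saprotroph"),
    g("Solicoccozyma", "yeast"),
    g("Glomus", "AM"),
    g("Phialocephala", "root endophyte"),
    g("Alternaria", "leaf pathogen"),
    g("Fusarium", NA, multi = TRUE),
    g("Fusarium", "leaf pathogen", species = "oxysporum")
  )
}

# Genus -> rank path lookup for the synthetic taxonomy truth.
synthetic_ranks <- function() {
  r <- function(genus, phylum, class, order, family) {
    tibble(kingdom = "Fungi", phylum = phylum, class = class, order = order,
           family = family, genus = genus)
  }
  dplyr::bind_rows(
    r("Russula", "Basidiomycota", "Agaricomycetes", "Russulales", "Russulaceae"),
    r("Lactarius", "Basidiomycota", "Agaricomycetes", "Russulales", "Russulaceae"),
    r("Inocybe", "Basidiomycota", "Agaricomycetes", "Agaricales", "Inocybaceae"),
    r("Cortinarius", "Basidiomycota", "Agaricomycetes", "Agaricales", "Cortinariaceae"),
    r("Tomentella", "Basidiomycota", "Agaricomycetes", "Thelephorales", "Thelephoraceae"),
    r("Amanita", "Basidiomycota", "Agaricomycetes", "Agaricales", "Amanitaceae"),
    r("Suillus", "Basidiomycota", "Agaricomycetes", "Boletales", "Suillaceae"),
    r("Hebeloma", "Basidiomycota", "Agaricomycetes", "Agaricales", "Hymenogastraceae"),
    r("Piloderma", "Basidiomycota", "Agaricomycetes", "Atheliales", "Atheliaceae"),
    r("Hyaloscypha", "Ascomycota", "Leotiomycetes", "Helotiales", "Hyaloscyphaceae"),
    r("Tuber", "Ascomycota", "Pezizomycetes", "Pezizales", "Tuberaceae"),
    r("Mortierella", "Mortierellomycota", "Mortierellomycetes", "Mortierellales", "Mortierellaceae"),
    r("Umbelopsis", "Mucoromycota", "Umbelopsidomycetes", "Umbelopsidales", "Umbelopsidaceae"),
    r("Mucor", "Mucoromycota", "Mucoromycetes", "Mucorales", "Mucoraceae"),
    r("Penicillium", "Ascomycota", "Eurotiomycetes", "Eurotiales", "Aspergillaceae"),
    r("Aspergillus", "Ascomycota", "Eurotiomycetes", "Eurotiales", "Aspergillaceae"),
    r("Trichoderma", "Ascomycota", "Sordariomycetes", "Hypocreales", "Hypocreaceae"),
    r("Mycena", "Basidiomycota", "Agaricomycetes", "Agaricales", "Mycenaceae"),
    r("Solicoccozyma", "Basidiomycota", "Tremellomycetes", "Filobasidiales", "Piskurozymaceae"),
    r("Glomus", "Glomeromycota", "Glomeromycetes", "Glomerales", "Glomeraceae"),
    r("Phialocephala", "Ascomycota", "Leotiomycetes", "Helotiales", "Mollisiaceae"),
    r("Alternaria", "Ascomycota", "Dothideomycetes", "Pleosporales", "Pleosporaceae"),
    r("Fusarium", "Ascomycota", "Sordariomycetes", "Hypocreales", "Nectriaceae")
  )
}

#' Configuration for a synthetic survey
#'
#' Defaults reproduce the study conditions the generator emulates: a few
#' hundred plots, sequencing depth lognormal with mean ~2421 and SD ~1243
#' reads clamped to \[504, 12763\], soil pH spanning the acid-to-calcareous
#' gradient, Gaussian OTU niches along pH, a few percent of mold-spoiled
#' and low-depth samples, and a handful of negative/positive controls.
#'
#' @param n_plots Number of field plots (>= 2).
#' @param n_otus Number of OTUs (>= 2).
#' @param n_control_samples Number of appended control samples (split
#'   between negative and mock-community positive controls).
#' @param depth_log_mean,depth_log_sd Natural-log mean and SD of per-sample
#'   read depth (defaults chosen so the clamped lognormal has mean ~2421
#'   and SD ~1243 reads).
#' @param min_depth_truth,max_depth_truth Clamp bounds on drawn depths
#'   (reads).
#' @param frac_spoiled Fraction of plots that receive an injected mold
#'   bloom exceeding the group's flagging threshold.
#' @param frac_low_depth Fraction of plots downsampled below 500 reads.
#' @param pH_range Length-2 interval of soil pH (KCl scale), within
#'   \[2, 9\].
#' @param niche_width_range Length-2 interval of Gaussian niche widths
#'   (pH units, > 0).
#' @param frac_host_linked Fraction of ectomycorrhizal OTUs whose
#'   abundance is multiplied by their host tree's basal-area proportion.
#' @param multi_otu_spoilage If `TRUE`, spoiled samples receive a bloom
#'   spread over several OTUs of the mold group rather than a single OTU.
#' @param spatial_structure If `TRUE`, adds a smooth spatial gradient to
#'   OTU expected abundances; off by default (no regional autocorrelation
#'   strength is assumed).
#' @param seed Integer seed; all three generation stages derive their
#'   streams from it.
#' @return A `survey_config` list, validated.
#' @export
survey_config <- function(n_plots = 200, n_otus = 150,
                          n_control_samples = 6,
                          depth_log_mean = 7.675, depth_log_sd = 0.484,
                          min_depth_truth = 504, max_depth_truth = 12763,
                          frac_spoiled = 0.05, frac_low_depth = 0.03,
                          pH_range = c(3, 8),
                          niche_width_range = c(0.6, 1.6),
                          frac_host_linked = 0.5,
                          multi_otu_spoilage = FALSE,
                          spatial_structure = FALSE,
                          seed = 1L) {
  cfg <- list(n_plots = as.integer(n_plots), n_otus = as.integer(n_otus),
              n_control_samples = as.integer(n_control_samples),
              depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
              min_depth_truth = min_depth_truth,
              max_depth_truth = max_depth_truth,
              frac_spoiled = frac_spoiled, frac_low_depth = frac_low_depth,
              pH_range = pH_range, niche_width_range = niche_width_range,
              frac_host_linked = frac_host_linked,
              multi_otu_spoilage = isTRUE(multi_otu_spoilage),
              spatial_structure = isTRUE(spatial_structure),
              seed = as.integer(seed))
  if (cfg$n_plots < 2) abort("`n_plots` must be >= 2.")
  if (cfg$n_otus < 2) abort("`n_otus` must be >= 2.")
  fr <- c(cfg$frac_spoiled, cfg$frac_low_depth, cfg$frac_host_linked)
  if (any(fr < 0 | fr > 1)) abort("Fractions must lie in [0, 1].")
  if (cfg$frac_spoiled + cfg$frac_low_depth > 1) {
    abort("`frac_spoiled` + `frac_low_depth` must not exceed 1.")
  }
  if (length(cfg$pH_range) != 2 || cfg$pH_range[1] >= cfg$pH_range[2] ||
      cfg$pH_range[1] < 2 || cfg$pH_range[2] > 9) {
    abort("`pH_range` must be an increasing interval within [2, 9].")
  }
  if (any(cfg$niche_width_range <= 0)) {
    abort("Niche widths must be positive.")
  }
  structure(cfg, class = "survey_config")
}

#' Generate the per-plot environment table
#'
#' One record per plot: soil pH uniform over the configured range; Ca, Mg,
#' P, K lognormal with Ca constructed rank-correlated with pH (calcareous
#' soils are base-rich); C and N lognormal with the C/N ratio negatively
#' related to pH; stable-isotope values normal; tree basal-area
#' proportions drawn from a habitat-specific simplex (treeless habitats
#' often have none) with the ectomycorrhizal plant percentage as the sum
#' over EcM tree genera; coordinates uniform on a rectangle; sampling
#' dates spread over two seasons; a small set of collectors.
#'
#' @param config A [survey_config()].
#' @return Tibble with one row per plot, derived log-ratios
#'   (`ln_CN`, `ln_CP`, `ln_NP`) included, and `is_control = FALSE`.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(config$seed)
  n <- config$n_plots
  id <- sprintf("plot_%04d", seq_len(n))

  z <- rnorm(n)                       # latent acidity axis
  pH <- config$pH_range[1] + diff(config$pH_range) * stats::pnorm(z)
  Ca <- exp(log(900) + 0.9 * (0.8 * z + 0.6 * rnorm(n)))
  Mg <- exp(log(120) + 0.7 * (0.4 * z + 0.9 * rnorm(n)))
  P  <- exp(log(40) + 0.8 * rnorm(n))
  K  <- exp(log(100) + 0.6 * rnorm(n))
  C_pct <- exp(log(4.5) + 0.55 * rnorm(n))
  CN <- exp(log(15) - 0.22 * z + 0.18 * rnorm(n))
  N_pct <- C_pct / CN
  d15N <- rnorm(n, 2.5, 2)
  d13C <- rnorm(n, -27, 1)

  habitat <- sample(habitat_types(), n, replace = TRUE,
                    prob = c(0.38, 0.08, 0.08, 0.12, 0.08, 0.06, 0.04,
                             0.04, 0.06, 0.06))
  treeless_p <- ifelse(habitat %in% c("grassland", "cropland", "bog",
                                      "wasteland", "ruin"), 0.7, 0)
  no_trees <- runif(n) < treeless_p
  genera <- tree_genera()
  alpha <- setNames(c(2, 2, 2, 1, 1, 0.7, 0.7, 0.5, 0.7, 0.5), genera)
  tree <- t(vapply(seq_len(n), function(i) {
    if (no_trees[i]) return(setNames(numeric(length(genera)), genera))
    gam <- stats::rgamma(length(genera), shape = alpha)
    # keep stands uneven: zero out a random subset of minor genera
    keep <- runif(length(genera)) < 0.6
    keep[which.max(gam)] <- TRUE
    gam[!keep] <- 0
    100 * gam / sum(gam)
  }, numeric(length(genera))))
  colnames(tree) <- paste0(genera, "_pct")
  ecm_pct <- rowSums(tree[, paste0(ecm_tree_genera(), "_pct"), drop = FALSE])

  dates <- as.Date("2018-05-01") +
    sample(0:520, n, replace = TRUE)
  meta <- tibble(
    sample_id = id,
    x = runif(n, 0, 250000), y = runif(n, 0, 150000),
    date = dates,
    collector = sample(paste0("collector_", 1:4), n, replace = TRUE),
    habitat_type = habitat,
    managed = runif(n) < 0.4,
    vegetation_age = round(runif(n, 5, 220)),
    plant_richness = stats::rpois(n, lambda = ifelse(no_trees, 6, 12)),
    pH_KCl = pH, P = P, K = K, Mg = Mg, Ca = Ca,
    C_pct = C_pct, N_pct = N_pct, d15N = d15N, d13C = d13C,
    ln_CN = log(C_pct / N_pct), ln_CP = log(C_pct / P),
    ln_NP = log(N_pct / P))
  meta <- dplyr::bind_cols(meta, as_tibble(tree))
  meta$ecm_plant_pct <- ecm_pct
  meta$is_control <- FALSE
  meta
}

# Assign genera to OTUs so every mold group and several EcM genera are
# represented, then draw niche parameters and host links.
draw_otu_truth <- function(metadata, config) {
  n_otu <- config$n_otus
  otu_id <- sprintf("otu_%04d", seq_len(n_otu))
  ranks <- synthetic_ranks()
  traits <- synthetic_traits()
  core <- c("Mortierella", "Mortierella", "Umbelopsis", "Umbelopsis",
            "Mucor", "Penicillium", "Penicillium", "Aspergillus",
            "Russula", "Inocybe", "Tomentella", "Cortinarius",
            "Hyaloscypha", "Hyaloscypha", "Mycena", "Glomus")
  pool <- ranks$genus
  w <- ifelse(pool %in% c("Mortierella", "Umbelopsis", "Mucor",
                          "Penicillium", "Aspergillus"), 0.5,
              ifelse(pool %in% traits$genus[traits$guild %in% "EcM"], 1.5, 1))
  genus <- c(core, sample(pool, max(0, n_otu - length(core)),
                          replace = TRUE, prob = w))[seq_len(n_otu)]

  tax <- dplyr::left_join(tibble(otu_id = otu_id, genus = genus),
                          ranks, by = "genus") |>
    dplyr::relocate("otu_id", "kingdom", "phylum", "class", "order",
                    "family", "genus")
  tax$species <- dplyr::if_else(tax$genus == "Fusarium", "oxysporum",
                                NA_character_)
  tax <- annotate_function(tax, traits)

  is_ecm <- !is.na(tax$guild) & tax$guild == "EcM"
  host <- rep(NA_character_, n_otu)
  linked <- is_ecm & runif(n_otu) < config$frac_host_linked
  host[linked] <- sample(ecm_tree_genera(), sum(linked), replace = TRUE)

  # Optima are drawn from a pool extending 1.5 pH units beyond the sampled
  # range: the regional species pool is wider than any one gradient, and a
  # flat community background within the range keeps relative abundances
  # interpretable. Mold OTUs get moderate base abundances (molds are
  # ubiquitous at the few-percent level; only spoilage makes a single mold
  # OTU dominant).
  is_mold <- !is.na(tax$mold_group)
  base <- rlnorm(n_otu, meanlog = 0, sdlog = 1)
  base[is_mold] <- rlnorm(sum(is_mold), meanlog = 0.3, sdlog = 0.5)
  truth <- tibble(
    otu_id = otu_id,
    niche_optimum = runif(n_otu, config$pH_range[1] - 1.5,
                          config$pH_range[2] + 1.5),
    niche_width = runif(n_otu, config$niche_width_range[1],
                        config$niche_width_range[2]),
    host_taxon = host,
    base_abundance = base)
  list(taxonomy = tax, truth_otus = truth)
}

#' Generate the OTU count table with Gaussian pH niches
#'
#' Expected relative abundance of OTU *i* in plot *s* is proportional to
#' `base_i * exp(-(pH_s - opt_i)^2 / (2 w_i^2))`, multiplied, for
#' host-linked ectomycorrhizal OTUs, by the host tree's basal-area
#' proportion (zero where the host is absent). Counts are drawn
#' multinomially at a lognormal depth clamped to the configured bounds.
#' OTUs carry a full truth taxonomy and functional annotation consistent
#' with [synthetic_traits()].
#'
#' @param metadata Output of [generate_environment()].
#' @param config The same [survey_config()].
#' @return List with `counts` (wide OTU tibble), `taxonomy` (truth
#'   assignments), `truth_otus` (niche parameters and host links) and
#'   `truth_samples` (flags, all `FALSE` before artifact injection).
#' @export
generate_otu_table <- function(metadata, config) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(config$seed + 1L)
  drawn <- draw_otu_truth(metadata, config)
  truth <- drawn$truth_otus
  n <- nrow(metadata)

  expected <- outer(metadata$pH_KCl, truth$niche_optimum, "-")
  expected <- exp(-(expected^2) / (2 * matrix(truth$niche_width^2, n,
                                              config$n_otus, byrow = TRUE)))
  expected <- expected * matrix(truth$base_abundance, n, config$n_otus,
                                byrow = TRUE)
  for (i in which(!is.na(truth$host_taxon))) {
    expected[, i] <- expected[, i] *
      metadata[[paste0(truth$host_taxon[i], "_pct")]] / 100
  }
  if (config$spatial_structure) {
    grad <- stats::plogis(scale(metadata$x + metadata$y)[, 1])
    expected <- expected * outer(grad, runif(config$n_otus, 0.5, 2), "^")
  }
  if (any(rowSums(expected) <= 0)) {
    abort("Internal error: all-zero expected abundance row.")
  }
  depth <- pmin(pmax(round(rlnorm(n, config$depth_log_mean,
                                  config$depth_log_sd)),
                     config$min_depth_truth), config$max_depth_truth)
  counts <- t(vapply(seq_len(n), function(s) {
    rmultinom(1, size = depth[s], prob = expected[s, ])[, 1]
  }, numeric(config$n_otus)))
  dimnames(counts) <- list(metadata$sample_id, truth$otu_id)

  truth_samples <- tibble(sample_id = metadata$sample_id,
                          spoiled_flag = FALSE,
                          spoiling_mold_group = NA_character_,
                          control_flag = FALSE, low_depth_flag = FALSE)
  list(counts = as_otu_table(counts), taxonomy = drawn$taxonomy,
       truth_otus = truth, truth_samples = truth_samples)
}

#' Inject spoilage, low-depth and control artifacts
#'
#' Mimics the failure modes a real survey must screen out: for a fraction
#' of plots one mold OTU of a designated group is inflated so its
#' within-sample share lands uniformly in (threshold, 0.9]; a fraction of
#' plots is downsampled below 500 reads; and control samples are appended
#' (negative controls: <= 50 reads of random noise; positive controls: a
#' fixed 8-OTU mock community).
#'
#' @param tab Output of [generate_otu_table()] (list with counts,
#'   taxonomy, truth tables).
#' @param metadata Output of [generate_environment()].
#' @param config The same [survey_config()].
#' @param thresholds [qc_thresholds()] whose group limits define the
#'   spoilage inflation floor.
#' @return List like `tab` but with modified `counts` and updated
#'   `truth_samples` (control rows included).
#' @export
inject_artifacts <- function(tab, metadata, config,
                             thresholds = qc_thresholds()) {
  stopifnot(inherits(config, "survey_config"))
  set.seed(config$seed + 2L)
  m <- otu_matrix(tab$counts)
  truth <- tab$truth_samples
  tax <- tab$taxonomy

  grp_lim <- c(Mortierellales = thresholds$mortierellales_max,
               Umbelopsidales = thresholds$umbelopsidales_max,
               Pezizomycotina_mold = thresholds$pezizomycotina_max)
  n <- nrow(m)
  n_spoil <- floor(config$frac_spoiled * n)
  n_low <- floor(config$frac_low_depth * n)
  pick <- sample(rownames(m), n_spoil + n_low)
  spoil_ids <- head(pick, n_spoil)
  low_ids <- setdiff(pick, spoil_ids)

  for (s in spoil_ids) {
    grp <- sample(names(grp_lim), 1)
    cand <- tax$otu_id[!is.na(tax$mold_group) & tax$mold_group == grp]
    if (!length(cand)) {
      abort(paste0("No OTUs of mold group '", grp,
                   "' available for spoilage injection; increase `n_otus`."))
    }
    target_share <- runif(1, grp_lim[[grp]] + 0.02, 0.9)
    if (config$multi_otu_spoilage && length(cand) > 1) {
      # spread the bloom but keep one OTU above the flagging threshold
      lead <- cand[sample.int(length(cand), 1)]
      rest <- setdiff(cand, lead)
      other <- sum(m[s, setdiff(colnames(m), cand)])
      m[s, lead] <- ceiling(target_share / (1 - target_share) * other)
      m[s, rest] <- m[s, rest] + stats::rpois(length(rest), other * 0.05)
    } else {
      otu <- cand[sample.int(length(cand), 1)]
      other <- sum(m[s, setdiff(colnames(m), otu)])
      m[s, otu] <- ceiling(target_share / (1 - target_share) * other)
    }
    truth$spoiled_flag[truth$sample_id == s] <- TRUE
    truth$spoiling_mold_group[truth$sample_id == s] <- grp
  }
  for (s in low_ids) {
    new_depth <- sample(50:499, 1)
    m[s, ] <- as.numeric(vegan::rrarefy(m[s, , drop = FALSE], new_depth))
    truth$low_depth_flag[truth$sample_id == s] <- TRUE
  }

  n_ctl <- config$n_control_samples
  if (n_ctl > 0) {
    n_neg <- ceiling(n_ctl / 2)
    ctl <- matrix(0, n_ctl, ncol(m),
                  dimnames = list(c(sprintf("control_neg_%02d",
                                            seq_len(n_neg)),
                                    if (n_ctl > n_neg)
                                      sprintf("control_pos_%02d",
                                              seq_len(n_ctl - n_neg))),
                                  colnames(m)))
    for (i in seq_len(n_neg)) {
      n_reads <- sample(0:50, 1)
      if (n_reads > 0) {
        hit <- sample(ncol(m), min(5, ncol(m)))
        ctl[i, hit] <- rmultinom(1, n_reads, rep(1, length(hit)))[, 1]
      }
    }
    if (n_ctl > n_neg) {
      mock <- head(seq_len(ncol(m)), 8)
      for (i in (n_neg + 1):n_ctl) {
        ctl[i, mock] <- rmultinom(1, 3000, rep(1, length(mock)))[, 1]
      }
    }
    m <- rbind(m, ctl)
    truth <- dplyr::bind_rows(
      truth,
      tibble(sample_id = rownames(ctl), spoiled_flag = FALSE,
             spoiling_mold_group = NA_character_, control_flag = TRUE,
             low_depth_flag = FALSE))
  }
  tab$counts <- as_otu_table(m)
  tab$truth_samples <- truth
  tab
}

#' Simulate a complete synthetic survey
#'
#' Runs [generate_environment()], [generate_otu_table()] and
#' [inject_artifacts()] and assembles the bundle the rest of the pipeline
#' consumes, with control samples present in both counts and metadata
#' (`is_control = TRUE`, environmental fields `NA`).
#'
#' @param config A [survey_config()].
#' @return A `fungal_survey` list: `counts`, `metadata`, `taxonomy`,
#'   `truth_otus`, `truth_samples`, `config`.
#' @export
simulate_survey <- function(config = survey_config()) {
  meta <- generate_environment(config)
  tab <- generate_otu_table(meta, config)
  tab <- inject_artifacts(tab, meta, config)
  ctl_ids <- tab$truth_samples$sample_id[tab$truth_samples$control_flag]
  if (length(ctl_ids)) {
    meta <- dplyr::bind_rows(meta,
                             tibble(sample_id = ctl_ids, is_control = TRUE))
  }
  structure(list(counts = tab$counts, metadata = meta,
                 taxonomy = tab$taxonomy, truth_otus = tab$truth_otus,
                 truth_samples = tab$truth_samples, config = config),
            class = "fungal_survey")
}
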