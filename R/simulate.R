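# Seeded synthetic scat-read generator with known ground truth.
#
# Emulates the data structure of a triplicate-PCR vertebrate metabarcoding
# diet study: two defecator species, ~30 scats each, 3 PCR replicates per
# scat, a ~20-taxon prey pool, defecator-dominated read counts, occasional
# second-carnivore contamination, tag-jump noise and per-replicate dropout
# of rare taxa.

#' Default taxonomy for the simulator
#'
#' Twenty vertebrate prey taxa across three classes (mammals, birds, one
#' amphibian; two reported only to genus) plus four mammalian carnivores
#' flagged as candidate defecators.
#'
#' @return A [taxonomy_table()].
#' @export
default_scat_taxonomy <- function() {
  row <- function(id, cl, or, fa, ge, sp, carn = FALSE)
    data.frame(taxon_id = id, class_name = cl, order_name = or,
               family_name = fa, genus_name = ge, species_name = sp,
               candidate_defecator = carn, stringsAsFactors = FALSE)
  taxonomy_table(rbind(
    # candidate defecators
    row("Vulpes vulpes", "Mammalia", "Carnivora", "Canidae", "Vulpes", "Vulpes vulpes", TRUE),
    row("Canis latrans", "Mammalia", "Carnivora", "Canidae", "Canis", "Canis latrans", TRUE),
    row("Lynx rufus", "Mammalia", "Carnivora", "Felidae", "Lynx", "Lynx rufus", TRUE),
    row("Martes caurina", "Mammalia", "Carnivora", "Mustelidae", "Martes", "Martes caurina", TRUE),
    # mammalian prey
    row("Callospermophilus lateralis", "Mammalia", "Rodentia", "Sciuridae", "Callospermophilus", "Callospermophilus lateralis"),
    row("Tamias sp.", "Mammalia", "Rodentia", "Sciuridae", "Tamias", ""),
    row("Tamiasciurus douglasii", "Mammalia", "Rodentia", "Sciuridae", "Tamiasciurus", "Tamiasciurus douglasii"),
    row("Glaucomys oregonensis", "Mammalia", "Rodentia", "Sciuridae", "Glaucomys", "Glaucomys oregonensis"),
    row("Peromyscus maniculatus", "Mammalia", "Rodentia", "Cricetidae", "Peromyscus", "Peromyscus maniculatus"),
    row("Myodes californicus", "Mammalia", "Rodentia", "Cricetidae", "Myodes", "Myodes californicus"),
    row("Microtus sp.", "Mammalia", "Rodentia", "Cricetidae", "Microtus", ""),
    row("Phenacomys intermedius", "Mammalia", "Rodentia", "Cricetidae", "Phenacomys", "Phenacomys intermedius"),
    row("Thomomys talpoides", "Mammalia", "Rodentia", "Geomyidae", "Thomomys", "Thomomys talpoides"),
    row("Zapus trinotatus", "Mammalia", "Rodentia", "Zapodidae", "Zapus", "Zapus trinotatus"),
    row("Aplodontia rufa", "Mammalia", "Rodentia", "Aplodontiidae", "Aplodontia", "Aplodontia rufa"),
    row("Lepus americanus", "Mammalia", "Lagomorpha", "Leporidae", "Lepus", "Lepus americanus"),
    row("Odocoileus hemionus", "Mammalia", "Artiodactyla", "Cervidae", "Odocoileus", "Odocoileus hemionus"),
    row("Sorex trowbridgii", "Mammalia", "Eulipotyphla", "Soricidae", "Sorex", "Sorex trowbridgii"),
    row("Scapanus latimanus", "Mammalia", "Eulipotyphla", "Talpidae", "Scapanus", "Scapanus latimanus"),
    # birds
    row("Dendragapus fuliginosus", "Aves", "Galliformes", "Phasianidae", "Dendragapus", "Dendragapus fuliginosus"),
    row("Turdus migratorius", "Aves", "Passeriformes", "Turdidae", "Turdus", "Turdus migratorius"),
    row("Junco hyemalis", "Aves", "Passeriformes", "Passerellidae", "Junco", "Junco hyemalis"),
    row("Colaptes auratus", "Aves", "Piciformes", "Picidae", "Colaptes", "Colaptes auratus"),
    # amphibian
    row("Rana cascadae", "Amphibia", "Anura", "Ranidae", "Rana", "Rana cascadae")
  ))
}

#' Simulation parameters
#'
#' A stated world for the generator; the defaults describe a realistic
#' triplicate-PCR scat metabarcoding study and are the conditions under
#' which the pipeline is validated.
#'
#' @param n_scats_per_species scats per defecator species (default 30).
#' @param defecator_taxa two distinct flagged carnivore taxa.
#' @param prey_pool character vector of prey taxon ids; default: the 20 prey
#'   taxa of [default_scat_taxonomy()].
#' @param prey_weights optional availability weights over `prey_pool`;
#'   default: one Dirichlet(concentration 1) draw from the seeded stream.
#' @param species_prey_weights optional named list (defecator taxon ->
#'   weight vector over `prey_pool`) giving each species its own prey
#'   availability; used to wire analytic utilization vectors into the
#'   generator for overlap-recovery studies.
#' @param lambda_richness per-scat prey richness is `1 + Poisson(lambda)`,
#'   truncated at the pool size (default 1.5).
#' @param dirichlet_alpha concentration of the within-scat prey proportions
#'   (default 1).
#' @param defecator_beta shape parameters `(a, b)` of the Beta-distributed
#'   defecator read fraction (default `c(8, 2)`, mean 0.8).
#' @param depth_median,depth_log_sd replicate depth is log-normal with this
#'   median and log-sd, rounded (defaults 20000 and 0.5).
#' @param dropout_d0,dropout_r0 a taxon at true replicate proportion `r`
#'   fails detection in a replicate with probability `d0 * exp(-r / r0)`
#'   (defaults 0.5 and 0.02): rare taxa drop out more.
#' @param contamination_prob probability a scat carries reads of a second
#'   carnivore (default 0.1) at read fraction `Uniform(0, contamination_fmax)`
#'   (default 0.08).
#' @param tagjump_rate expected fraction of each replicate's reads reassigned
#'   to taxa drawn uniformly from the full taxonomy, conserving depth
#'   (default 0.002).
#' @param failed_replicate_prob probability a replicate's depth is resampled
#'   uniformly below `failed_replicate_depth_max` (defaults 0.05 and 1000),
#'   emulating failed amplification.
#' @param n_replicates PCR replicates per scat (default 3).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param taxonomy a [taxonomy_table()] containing all referenced taxa.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_scats_per_species = 30L,
                              defecator_taxa = c("Vulpes vulpes", "Canis latrans"),
                              prey_pool = NULL,
                              prey_weights = NULL,
                              species_prey_weights = NULL,
                              lambda_richness = 1.5,
                              dirichlet_alpha = 1.0,
                              defecator_beta = c(8, 2),
                              depth_median = 20000,
                              depth_log_sd = 0.5,
                              dropout_d0 = 0.5,
                              dropout_r0 = 0.02,
                              contamination_prob = 0.1,
                              contamination_fmax = 0.08,
                              tagjump_rate = 0.002,
                              failed_replicate_prob = 0.05,
                              failed_replicate_depth_max = 1000L,
                              n_replicates = 3L,
                              seed = 1L,
                              taxonomy = default_scat_taxonomy()) {
  if (length(defecator_taxa) != 2L || defecator_taxa[1] == defecator_taxa[2])
    stop("defecator_taxa must be two distinct taxa", call. = FALSE)
  if (!all(defecator_taxa %in% carnivore_ids(taxonomy)))
    stop("defecator_taxa must be flagged candidate carnivores in the taxonomy",
         call. = FALSE)
  if (is.null(prey_pool))
    prey_pool <- setdiff(taxonomy$taxon_id, carnivore_ids(taxonomy))
  if (!all(prey_pool %in% taxonomy$taxon_id))
    stop("prey_pool contains taxa absent from the taxonomy", call. = FALSE)
  if (!is.null(prey_weights) && length(prey_weights) != length(prey_pool))
    stop("prey_weights must match prey_pool in length", call. = FALSE)
  if (!is.null(species_prey_weights)) {
    if (!all(names(species_prey_weights) %in% defecator_taxa) ||
        !all(vapply(species_prey_weights, length, 1L) == length(prey_pool)))
      stop("species_prey_weights must map each defecator to a weight vector over prey_pool",
           call. = FALSE)
  }
  if (lambda_richness <= 0) stop("lambda_richness must be > 0", call. = FALSE)
  for (p in c("dropout_d0", "contamination_prob", "tagjump_rate",
              "failed_replicate_prob"))
    assert_proportion(get(p), p, open_lower = FALSE, open_upper = FALSE)
  assert_proportion(contamination_fmax, "contamination_fmax",
                    open_lower = FALSE)
  if (depth_median < 1) stop("depth_median must be >= 1", call. = FALSE)

  structure(list(
    n_scats_per_species = as.integer(n_scats_per_species),
    defecator_taxa = defecator_taxa,
    prey_pool = prey_pool,
    prey_weights = prey_weights,
    species_prey_weights = species_prey_weights,
    lambda_richness = lambda_richness,
    dirichlet_alpha = dirichlet_alpha,
    defecator_beta = defecator_beta,
    depth_median = depth_median,
    depth_log_sd = depth_log_sd,
    dropout_d0 = dropout_d0,
    dropout_r0 = dropout_r0,
    contamination_prob = contamination_prob,
    contamination_fmax = contamination_fmax,
    tagjump_rate = tagjump_rate,
    failed_replicate_prob = failed_replicate_prob,
    failed_replicate_depth_max = as.numeric(failed_replicate_depth_max),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    taxonomy = taxonomy
  ), class = "simulation_params")
}

#' Simulate a synthetic scat-read dataset with ground truth
#'
#' For each scat: a true prey set (richness `1 + Poisson(lambda)`, taxa drawn
#' without replacement from the availability weights) with Dirichlet
#' within-scat proportions and a Beta-distributed defecator read fraction;
#' each replicate is a multinomial draw of its log-normal depth over
#' (defecator, prey scaled by `1 - defecator fraction`, optional contaminant
#' carnivore), followed by per-taxon dropout zeroing and tag-jump
#' reassignment. Per-scat substreams are derived deterministically from the
#' seed, so enlarging the design never perturbs earlier scats.
#'
#' @param params a [simulation_params()].
#' @return list with `counts` (a [read_count_table()]), `truth` (per-scat
#'   true defecator, prey sets/proportions, contamination log, per-species
#'   true [diet profiles][build_diet_profile] over true compositions) and
#'   `taxonomy`.
#' @export
simulate_scats <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  taxonomy <- params$taxonomy
  all_taxa <- taxonomy$taxon_id
  carnivores <- carnivore_ids(taxonomy)
  pool <- params$prey_pool
  n_per <- params$n_scats_per_species
  n_total <- 2L * n_per

  set.seed(params$seed)
  base_weights <- params$prey_weights %||% rdirichlet1(length(pool), 1)
  # per-(species, scat-index) substreams: enlarging either species leaves
  # every earlier scat of both species bit-identical
  scat_seeds <- lapply(seq_along(params$defecator_taxa), function(s)
    substream_seeds((params$seed + 987631L * s) %% (.Machine$integer.max - 1L),
                    n_per))

  species_weights <- function(sp) {
    w <- params$species_prey_weights[[sp]] %||% base_weights
    w / sum(w)
  }

  rows <- vector("list", n_total)
  truth_scats <- vector("list", n_total)
  contam_log <- list()
  idx <- 0L
  for (s in seq_along(params$defecator_taxa)) {
    sp <- params$defecator_taxa[s]
    tag <- toupper(substr(sanitize_label(sp), 1, 2))
    w <- species_weights(sp)
    n_pos <- sum(w > 0)
    if (n_pos < 1L) stop("prey availability weights are all zero for ", sp,
                         call. = FALSE)
    for (i in seq_len(n_per)) {
      idx <- idx + 1L
      set.seed(scat_seeds[[s]][i])
      scat_id <- sprintf("%s_%03d", tag, i)

      # richness truncated at the number of available (positive-weight) taxa
      m <- min(1L + stats::rpois(1, params$lambda_richness), n_pos)
      prey <- sample(pool, m, prob = w)
      prop <- rdirichlet1(m, params$dirichlet_alpha)
      f_def <- stats::rbeta(1, params$defecator_beta[1], params$defecator_beta[2])

      contam_taxon <- NA_character_
      contam_frac <- 0
      if (stats::runif(1) < params$contamination_prob) {
        other <- setdiff(carnivores, sp)
        contam_taxon <- if (length(other) == 1L) other else sample(other, 1)
        contam_frac <- stats::runif(1, 0, params$contamination_fmax)
        contam_log[[length(contam_log) + 1L]] <- data.frame(
          scat_id = scat_id, contaminant = contam_taxon,
          fraction = contam_frac, stringsAsFactors = FALSE)
      }

      comp_taxa <- c(sp, prey, if (!is.na(contam_taxon)) contam_taxon)
      comp <- c(f_def, (1 - f_def) * prop)
      if (!is.na(contam_taxon)) comp <- c((1 - contam_frac) * comp, contam_frac)
      comp <- comp / sum(comp)

      depths <- numeric(params$n_replicates)
      for (r in seq_len(params$n_replicates)) {
        depth <- if (stats::runif(1) < params$failed_replicate_prob) {
          max(1, round(stats::runif(1, 0, params$failed_replicate_depth_max)))
        } else {
          max(1, round(stats::rlnorm(1, log(params$depth_median),
                                     params$depth_log_sd)))
        }
        depths[r] <- depth
        cnt <- as.vector(stats::rmultinom(1, depth, comp))
        # per-replicate dropout: rare taxa fail detection more often
        if (params$dropout_d0 > 0) {
          p_drop <- params$dropout_d0 * exp(-comp / params$dropout_r0)
          cnt[stats::runif(length(cnt)) < p_drop] <- 0L
        }
        # tag jumping: reassign a binomial fraction of reads to taxa drawn
        # uniformly from the global pool, conserving depth
        tot <- sum(cnt)
        if (params$tagjump_rate > 0 && tot > 0) {
          n_tj <- stats::rbinom(1, tot, params$tagjump_rate)
          if (n_tj > 0) {
            src <- sample(rep.int(seq_along(cnt), cnt), n_tj)
            rm_tab <- tabulate(src, nbins = length(cnt))
            cnt <- cnt - rm_tab
            dst <- sample(all_taxa, n_tj, replace = TRUE)
            add_tab <- table(dst)
            extra_taxa <- names(add_tab)
            merged <- stats::setNames(cnt, comp_taxa)
            for (tx in extra_taxa) {
              merged[tx] <- (if (tx %in% names(merged)) merged[tx] else 0L) +
                as.integer(add_tab[[tx]])
            }
            keep <- merged > 0
            rows[[idx]] <- rbind(rows[[idx]], data.frame(
              scat_id = scat_id, replicate = r,
              taxon_id = names(merged)[keep],
              reads = as.integer(merged[keep]), stringsAsFactors = FALSE))
            next
          }
        }
        keep <- cnt > 0
        rows[[idx]] <- rbind(rows[[idx]], data.frame(
          scat_id = scat_id, replicate = r, taxon_id = comp_taxa[keep],
          reads = as.integer(cnt[keep]), stringsAsFactors = FALSE))
      }

      truth_scats[[idx]] <- list(scat_id = scat_id, defecator = sp,
                                 prey = prey, proportions = stats::setNames(prop, prey),
                                 defecator_fraction = f_def,
                                 contaminant = contam_taxon,
                                 contaminant_fraction = contam_frac,
                                 replicate_depths = depths)
    }
  }

  counts <- suppressMessages(
    read_count_table(do.call(rbind, rows), taxonomy = taxonomy))

  truth <- list(
    scats = truth_scats,
    defecator = stats::setNames(
      vapply(truth_scats, `[[`, "", "defecator"),
      vapply(truth_scats, `[[`, "", "scat_id")),
    contamination = if (length(contam_log)) do.call(rbind, contam_log) else
      data.frame(scat_id = character(0), contaminant = character(0),
                 fraction = numeric(0), stringsAsFactors = FALSE),
    profiles = true_profiles(truth_scats, params$defecator_taxa)
  )
  list(counts = counts, truth = truth, taxonomy = taxonomy)
}

# True FOO/wPOO per species from the true prey sets (presence-based).
#' @noRd
true_profiles <- function(truth_scats, species) {
  out <- lapply(species, function(sp) {
    sets <- lapply(Filter(function(x) x$defecator == sp, truth_scats),
                   `[[`, "prey")
    n <- length(sets)
    tab <- table(unlist(lapply(sets, unique)))
    foo <- stats::setNames(as.numeric(tab) / n, names(tab))
    wp <- stats::setNames(numeric(length(tab)), names(tab))
    for (s in sets) for (k in unique(s)) wp[k] <- wp[k] + 1 / (length(unique(s)) * n)
    ord <- order(names(foo))
    structure(list(species_label = sp, n_scats = n,
                   foo = foo[ord], wpoo = wp[ord]),
              class = "diet_profile")
  })
  stats::setNames(out, species)
}

#' Construct two utilization vectors with known Pianka overlap
#'
#' `p` is uniform on categories `1..k`; a second uniform vector `r` lives on
#' the disjoint categories `k+1..2k`; `q = theta * p + (1 - theta) * r`. The
#' overlap of the pair is available in closed form,
#' `o_true = theta / sqrt(theta^2 + (1 - theta)^2)`, making the pair an
#' analytic test point for overlap estimation.
#'
#' @param theta mixing weight in `[0, 1]`.
#' @param k support size of each uniform block (>= 1).
#' @param seed unused (the construction is deterministic); accepted for
#'   interface uniformity.
#' @return list with `p`, `q` (named numeric over categories `cat01..`),
#'   and `o_true`.
#' @export
make_profiles_with_overlap <- function(theta, k, seed = NULL) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1)
    stop("theta must lie in [0, 1]", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  cats <- sprintf("cat%02d", seq_len(2L * k))
  p <- stats::setNames(c(rep(1 / k, k), rep(0, k)), cats)
  r <- stats::setNames(c(rep(0, k), rep(1 / k, k)), cats)
  q <- theta * p + (1 - theta) * r
  o_true <- if (theta == 0) 0 else theta / sqrt(theta^2 + (1 - theta)^2)
  list(p = p, q = q, o_true = o_true)
}
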