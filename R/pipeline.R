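#' Pipeline configuration
#'
#' All module thresholds in one place, echoed into the report bundle. A
#' single master seed deterministically derives per-stage seeds.
#'
#' @param prefilter_ani Membership ANI prefilter (percent).
#' @param ani_t,ddh_t Genomovar delineation cutoffs (percent).
#' @param softcore_frac,cloud_max Pan-genome category bin edges.
#' @param n_samples Rarefaction sample size per genome count.
#' @param posterior_threshold Likely-event posterior threshold.
#' @param min_identity,min_coverage Homolog clustering thresholds.
#' @param screen_identity,screen_coverage,screen_evalue Marker screen
#'   cutoffs.
#' @param n_random_trees Background trees for the topology concordance test.
#' @param seed Master seed.
#' @param ani Fragment comparison settings, an [ani_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(prefilter_ani = 80, ani_t = 94.5, ddh_t = 59.5,
                            softcore_frac = 0.95, cloud_max = 2,
                            n_samples = 20000, posterior_threshold = 0.5,
                            min_identity = 0.5, min_coverage = 0.5,
                            screen_identity = 0.5, screen_coverage = 0.7,
                            screen_evalue = 1e-5, n_random_trees = 1000,
                            seed = 1L, ani = ani_config()) {
  structure(as.list(environment()), class = "pipeline_config")
}

cache_get <- function(cache_dir, key, expr, log) {
  if (is.null(cache_dir)) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    log(cached = FALSE, secs = proc.time()[["elapsed"]] - t0)
    return(val)
  }
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(path)) {
    log(cached = TRUE, secs = 0)
    return(readRDS(path))
  }
  t0 <- proc.time()[["elapsed"]]
  val <- force(expr)
  saveRDS(val, path)
  log(cached = FALSE, secs = proc.time()[["elapsed"]] - t0)
  val
}

#' Run the full species-complex analysis
#'
#' Executes, in dependency order: fragment-based distances (ANI/dDDH),
#' genomovar delineation, homolog clustering and pan-genome
#' categorization, homolog-sharing fractions, rarefaction with curve fits,
#' the 100-ANI and concatenated-core NJ trees with their Kendall-Colijn
#' concordance test, gain-loss inference on the rooted core tree, an
#' optional marker-cluster screen and an optional taxonomy report. Stages
#' are cached by content hash when `cache_dir` is given; identical inputs
#' and configuration give an identical bundle.
#'
#' @param genomes Named list of `genome_record`s, a `complex_sim`, or a
#'   dataset directory (see [read_dataset()]).
#' @param config A [pipeline_config()].
#' @param cluster_queries Optional named ordered `AAStringSet` of marker
#'   proteins; defaults to the truth-set marker proteins when `genomes` is
#'   a simulation that implanted them.
#' @param declared,reference_names Optional name vectors for
#'   [taxonomy_report()].
#' @param cache_dir Optional stage-cache directory.
#' @return A `complex_report` list; see Details in the vignette.
#' @export
run_complex_analysis <- function(genomes, config = pipeline_config(),
                                 cluster_queries = NULL,
                                 declared = NULL, reference_names = NULL,
                                 cache_dir = NULL) {
  if (is.character(genomes)) genomes <- read_dataset(genomes)
  if (inherits(genomes, "complex_sim")) {
    cluster_queries <- cluster_queries %||% genomes$truth$marker_proteins
    genomes <- genomes$genomes
  }
  seeds <- derive_seeds(config$seed, 4)
  stage_log <- list()
  logger <- function(stage) function(cached, secs) {
    stage_log[[stage]] <<- tibble(stage = stage, cached = cached,
                                  seconds = round(secs, 2))
  }
  input_hash <- rlang::hash(lapply(genomes, function(g)
    list(g$id, as.character(g$contigs), g$genes)))
  key <- function(stage, ...) {
    paste0(stage, "-", substr(rlang::hash(list(input_hash, ...)), 1, 16))
  }

  dists <- cache_get(cache_dir, key("distances", config$ani),
                     genome_distances(genomes, config$ani),
                     logger("distances"))
  assignment <- cache_get(
    cache_dir, key("delineate", config$ani_t, config$ddh_t),
    delineate_genomovars(dists$ani, dists$ddh, config$ani_t, config$ddh_t),
    logger("delineate"))
  fams <- cache_get(
    cache_dir, key("cluster", config$min_identity, config$min_coverage),
    cluster_homologs(genomes, config$min_identity, config$min_coverage),
    logger("cluster"))
  pan <- pan_matrix(fams, genomes = names(genomes))
  categories <- categorize_pan(pan, config$softcore_frac, config$cloud_max)
  hf <- homolog_fraction(pan)
  rar <- cache_get(
    cache_dir, key("rarefy", config$n_samples, seeds[[1]]),
    rarefy(pan, n_samples = config$n_samples, seed = seeds[[1]]),
    logger("rarefy"))
  fits <- fit_curves(rar)
  scc <- single_copy_core(pan)
  core_dist <- cache_get(cache_dir, key("core_dist"),
                         concat_core_distance(genomes, fams, core = scc),
                         logger("core_dist"))
  ani_tree <- nj_tree(dists$ani_dist)
  core_tree <- nj_tree(core_dist)
  root_leaf <- sort(names(genomes))[1]
  rooted <- lapply(list(ani = ani_tree, core = core_tree), function(tr)
    ape::root(tr, outgroup = root_leaf, resolve.root = TRUE))
  kc <- kc_null_test(rooted$ani, rooted$core,
                     n_random = config$n_random_trees, seed = seeds[[2]])
  gl_model <- cache_get(
    cache_dir, key("gainloss", config$posterior_threshold),
    fit_gainloss(pan, rooted$core,
                 posterior_threshold = config$posterior_threshold),
    logger("gainloss"))
  events <- likely_events(branch_posteriors(pan, rooted$core, gl_model),
                          categories = categories)
  screen <- NULL
  if (!is.null(cluster_queries)) {
    screen <- cache_get(
      cache_dir, key("screen", as.character(cluster_queries)),
      screen_cluster(genomes, cluster_queries,
                     min_identity = config$screen_identity,
                     min_coverage = config$screen_coverage,
                     max_significance = config$screen_evalue),
      logger("screen"))
  }
  taxonomy <- NULL
  if (!is.null(declared) && !is.null(reference_names)) {
    taxonomy <- taxonomy_report(assignment, declared, reference_names)
  }

  accounting <- pan_accounting(categories)
  # conservation assertions: the bundle must be internally consistent
  tot <- category_totals(categories)
  assert_that(tot$cloud + tot$shell + tot$softcore == tot$pan_total,
              "category totals do not sum to pan size")
  assert_that(abs(sum(accounting$pct[accounting$category %in%
                                       c("cloud", "shell", "softcore")]) - 100) < 1e-6,
              "category percentages do not sum to 100")

  structure(list(
    config = config,
    distances = dists,
    assignment = assignment,
    genomovar_ranges = genomovar_range_table(dists$ani, dists$ddh, assignment),
    families = fams,
    pan = pan,
    categories = categories,
    accounting = accounting,
    homolog_fraction = hf,
    rarefaction = rar,
    fits = fits,
    trees = rooted,
    kc_test = kc,
    gainloss = gl_model,
    events = events,
    cluster_screen = screen,
    taxonomy = taxonomy,
    stage_log = bind_rows(stage_log)
  ), class = "complex_report")
}

#' @export
print.complex_report <- function(x, ...) {
  tot <- attr(x$events, "totals")
  cat(sprintf(paste0(
    "<complex_report> %d genomes, %d genomovars, pan %d families\n",
    "  pan-genome: %s (gamma = %.3f); likely events %d gains / %d losses\n"),
    ncol(x$pan), length(unique(x$assignment$genomovar)), nrow(x$pan),
    if (isTRUE(x$fits$pan$open)) "open" else "closed",
    x$fits$pan$coef[["gamma"]], tot$gains, tot$losses))
  invisible(x)
}

#' Pan-genome accounting table
#'
#' Category totals and shares of the pan-genome, with the softcore
#' subsuming the strict core (so cloud + shell + softcore = pan size, and
#' the strict-core share is reported out of the same total). Raw
#' percentages are accompanied by two printed-precision columns (two
#' decimals, one decimal) matching the mixed precision such tables are
#' reported with.
#'
#' @param x A `pan_categories` object, or a named numeric vector/list with
#'   entries strict_core, softcore (including strict core), shell, cloud.
#' @return Tibble: category, count, pct, pct_2dp, pct_1dp (the `accessory`
#'   row aggregates shell + cloud).
#' @export
pan_accounting <- function(x) {
  counts <- if (inherits(x, "pan_categories")) category_totals(x) else as.list(x)
  need <- c("strict_core", "softcore", "shell", "cloud")
  assert_that(all(need %in% names(counts)),
              "need counts strict_core, softcore, shell, cloud")
  assert_that(counts$strict_core <= counts$softcore,
              "strict core must be contained in softcore")
  total <- counts$softcore + counts$shell + counts$cloud
  rows <- tibble(
    category = c("strict_core", "softcore", "shell", "cloud", "accessory",
                 "pan_total"),
    count = c(counts$strict_core, counts$softcore, counts$shell,
              counts$cloud, counts$shell + counts$cloud, total)
  ) |>
    mutate(pct = 100 * count / total,
           pct_2dp = round(pct, 2), pct_1dp = round(pct, 1))
  rows
}

#' Within-genomovar ANI and dDDH ranges
#'
#' Minimum and maximum pairwise ANI and dDDH within each genomovar,
#' restricted to genomovars with at least `min_members` genomes (pairs are
#' meaningless below three members).
#'
#' @param ani,ddh `dist_matrix` objects.
#' @param assignment A `genomovar_assignment`.
#' @param min_members Minimum genomovar size to report (default 3).
#' @return Tibble: genomovar, n, ani_min, ani_max, ddh_min, ddh_max.
#' @export
genomovar_range_table <- function(ani, ddh, assignment, min_members = 3) {
  groups <- split(assignment$genome, assignment$genomovar)
  groups <- groups[lengths(groups) >= min_members]
  bind_rows(lapply(names(groups), function(gv) {
    g <- groups[[gv]]
    am <- unclass(ani)[g, g]; dm <- unclass(ddh)[g, g]
    up <- upper.tri(am)
    tibble(genomovar = gv, n = length(g),
           ani_min = min(am[up]), ani_max = max(am[up]),
           ddh_min = min(dm[up]), ddh_max = max(dm[up]))
  }))
}
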