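## Orchestration of the full workflow: genus-wide then per-clade
## lineage/character/disparity analyses, model tables and (optionally)
## convergence and geography, from one configuration into a directory of
## tab-separated reports.

#' Screen clades by minimum size
#'
#' @param tree a \code{timetree}.
#' @param clades named list of tip sets (validated for monophyly).
#' @param min_size minimum number of tips (default 25).
#' @return the eligible subset of \code{clades}.
#' @export
clade_screen <- function(tree, clades, min_size = 25) {
  if (!length(clades)) return(clades)
  validate_clades(tree, clades)
  clades[vapply(clades, length, 0L) >= min_size]
}

#' Run the full analysis pipeline
#'
#' Takes a configuration (a list, or a path to a YAML file with the same
#' fields), runs the configured stages on the whole tree and on each
#' eligible clade, and writes tab-separated tables plus a run manifest
#' into the output directory. Stages whose inputs are missing are
#' recorded as skipped (e.g. no trait table means no disparity analysis).
#'
#' Configuration fields: \code{tree} (path or \code{timetree}),
#' \code{traits}, \code{habitats}, \code{coords}, \code{clades} (paths or
#' objects; optional), \code{out_dir}, \code{seed}, and the optional
#' stage parameters \code{n_null} (gamma), \code{n_maps}, \code{n_sims},
#' \code{n_bins} (CTT), \code{dtt_sims}, \code{min_clade_size},
#' \code{shift_age} (trait models), \code{run_models},
#' \code{run_surface}, \code{run_geo}, \code{geo_ages}.
#'
#' @param config list or YAML path.
#' @return the output directory, invisibly; the clade summary table is
#'   written as \code{clade_summary.tsv}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configurations requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'")
  if (is.null(cfg$seed)) stop("config needs an explicit 'seed'")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  tree <- if (inherits(cfg$tree, "phylo")) as_timetree(cfg$tree) else
    read_timetree(cfg$tree)
  traits <- load_table(cfg$traits)
  habitats <- load_states(cfg$habitats)
  coords <- load_table(cfg$coords, keep_df = TRUE)
  clades <- load_clades(cfg$clades)

  n_null <- cfg$n_null %||% 1000
  n_maps <- cfg$n_maps %||% 100
  n_sims <- cfg$n_sims %||% 200
  n_bins <- cfg$n_bins %||% 50
  dtt_sims <- cfg$dtt_sims %||% 200
  min_size <- cfg$min_clade_size %||% 25
  seeds <- child_seeds(cfg$seed, 64)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  units <- list(list(name = "all", tree = tree))
  if (length(clades)) {
    eligible <- clade_screen(tree, clades, min_size)
    note("clades: %d configured, %d eligible (min size %d)",
         length(clades), length(eligible), min_size)
    for (nm in names(eligible)) {
      units <- c(units, list(list(name = nm,
                                  tree = extract_clade(tree, eligible[[nm]]))))
    }
  }

  mk <- NULL
  if (!is.null(habitats)) {
    mk <- fit_mk(tree, habitats, structure = "SYM")
  }

  rows <- list()
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    us <- child_seeds(seeds[[ui]], 8)
    row <- list(unit = u$name, ntip = length(u$tree$tip.label),
                gamma = NA_real_, gamma_p = NA_real_, ctt = "n.a.",
                n_habitats = NA_integer_, mdi = NA_real_,
                dtt_p_lo = NA_real_, dtt_p_hi = NA_real_)
    ## gamma / LTT
    g <- gamma_test(u$tree, n_null = n_null, seed = us[[1]])
    row$gamma <- g$gamma; row$gamma_p <- g$p_value
    utils::write.table(ltt_curve(u$tree),
                       file.path(cfg$out_dir, paste0("ltt_", u$name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ## CTT
    if (!is.null(mk)) {
      hab_u <- habitats[intersect(names(habitats), u$tree$tip.label)]
      if (sum(!is.na(hab_u)) >= 3 && length(unique(stats::na.omit(hab_u))) >= 2) {
        maps <- sample_stochastic_maps(u$tree, mk, hab_u, n_maps = n_maps,
                                       seed = us[[2]])
        ctt <- ctt_curve(maps, n_bins = n_bins)
        cttt <- ctt_null_test(u$tree, mk, ctt, n_sims = n_sims,
                              seed = us[[3]])
        row$ctt <- cttt$verdict
        row$n_habitats <- length(unique(stats::na.omit(hab_u)))
      } else {
        row$ctt <- "n.a."
        note("unit %s: CTT skipped (too few observed habitats)", u$name)
      }
    } else {
      row$ctt <- "n.a."
      if (ui == 1) note("CTT skipped: no habitat table")
    }
    ## DTT
    if (!is.null(traits)) {
      cover <- sum(stats::complete.cases(traits) &
                     rownames(traits) %in% u$tree$tip.label)
      if (cover >= max(4, 0.3 * length(u$tree$tip.label))) {
        dt <- dtt_test(u$tree, traits, n_sims = dtt_sims, seed = us[[4]])
        row$mdi <- dt$mdi
        row$dtt_p_lo <- dt$p_interval[1]; row$dtt_p_hi <- dt$p_interval[2]
      } else {
        note("unit %s: DTT skipped (too much missing trait data)", u$name)
      }
    } else if (ui == 1) note("DTT skipped: no trait table")
    rows[[ui]] <- row
  }
  summary <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.table(summary, file.path(cfg$out_dir, "clade_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## diversification model table
  if (isTRUE(cfg$run_models)) {
    specs <- diversification_model_set(mu = cfg$mu %||% 0)
    fits <- lapply(specs, function(s) fit_diversification(tree, s))
    tab <- compare_models(fits)
    est <- do.call(rbind, lapply(fits[tab$model], function(f)
      data.frame(la1 = f$estimates$la1, mu1 = f$estimates$mu1,
                 K1 = f$estimates$K1, la2 = f$estimates$la2,
                 mu2 = f$estimates$mu2, K2 = f$estimates$K2,
                 t_shift = f$estimates$t_shift %||% NA)))
    utils::write.table(cbind(tab, est),
                       file.path(cfg$out_dir, "model_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ## morphospace: clustering and trait models on phylogenetic PC scores
  if (!is.null(traits) && isTRUE(cfg$run_trait_models)) {
    ok <- rownames(traits)[stats::complete.cases(traits)]
    ptree <- as_timetree(ape::drop.tip(tree, setdiff(tree$tip.label, ok)))
    pp <- phylo_pca(ptree, traits)
    scores <- pp$scores[, 1:2]
    specs <- trait_model_set(cfg$shift_age %||% 15.5)
    tfits <- lapply(specs, function(s) fit_trait_model(ptree, scores, s))
    utils::write.table(compare_trait_models(tfits),
                       file.path(cfg$out_dir, "trait_model_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cl <- ward_clusters(traits, cfg$n_clusters %||% 9)
    utils::write.table(
      data.frame(tip = names(cl$labels), cluster = cl$labels),
      file.path(cfg$out_dir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ## convergence
  if (!is.null(traits) && isTRUE(cfg$run_surface)) {
    ok <- rownames(traits)[stats::complete.cases(traits)]
    ptree <- as_timetree(ape::drop.tip(tree, setdiff(tree$tip.label, ok)))
    pp <- phylo_pca(ptree, traits)
    sf <- run_surface(ptree, pp$scores[, 1:2],
                      max_shifts = cfg$max_shifts %||% 30)
    writeLines(utils::capture.output(print(sf)),
               file.path(cfg$out_dir, "surface.txt"))
  }
  ## geography
  if (!is.null(coords) && isTRUE(cfg$run_geo)) {
    ages <- cfg$geo_ages %||% c(45, 15)
    for (aage in ages) {
      rec <- geo_reconstruct(tree, coords, at_age = aage,
                             n_draws = cfg$geo_draws %||% 500,
                             seed = seeds[[40]] )
      cent <- do.call(rbind, lapply(rec, function(r)
        data.frame(target = r$target, lon = r$centroid$lon,
                   lat = r$centroid$lat, n = r$n_retained)))
      utils::write.table(cent,
                         file.path(cfg$out_dir,
                                   sprintf("geo_age%g.tsv", aage)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- c(sprintf("seed\t%d", cfg$seed),
                sprintf("date\t%s", format(Sys.time())),
                sprintf("R\t%s", R.version.string),
                log)
  writeLines(manifest, file.path(cfg$out_dir, "manifest.txt"))
  invisible(cfg$out_dir)
}

load_table <- function(x, keep_df = FALSE) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) x <- read_tip_table(x)
  if (keep_df) return(as.data.frame(x))
  as.matrix(as.data.frame(x))
}

load_states <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    tb <- read_tip_table(x)
    stats::setNames(as.character(tb[[1]]), rownames(tb))
  } else x
}

load_clades <- function(x) {
  if (is.null(x)) return(list())
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    tb <- utils::read.delim(x, stringsAsFactors = FALSE)
    split(tb$tip, tb$clade)
  } else x
}
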