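#' Run configuration for the end-to-end pipeline
#'
#' Collects every stage's parameters plus a master seed from which each
#' stochastic stage derives its own seed deterministically.
#'
#' @param sim a [sim_config()].
#' @param geometry a [barn_geometry()].
#' @param cleaning list of cleaning parameters (see [clean_pipeline()]).
#' @param protocol a [proximity_protocol()].
#' @param zones zones to analyse.
#' @param q permutation count for all inference.
#' @param block_days block size for temporal comparisons.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       geometry = barn_geometry(),
                       cleaning = list(),
                       protocol = proximity_protocol(),
                       zones = c("full_barn", "feeding", "non_feeding"),
                       q = 10000,
                       block_days = 4,
                       seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(geometry, "barn_geometry"),
            inherits(protocol, "proximity_protocol"), q >= 1)
  zones <- match.arg(zones, c("full_barn", "feeding", "non_feeding"),
                     several.ok = TRUE)
  sim$seed <- as.integer(seed)  # stage seeds derive from the master seed
  cfg <- list(sim = sim, geometry = geometry, cleaning = cleaning,
              protocol = protocol, zones = zones, q = as.integer(q),
              block_days = as.integer(block_days), seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

run_config_to_list <- function(config) {
  list(
    seed = config$seed, q = config$q, block_days = config$block_days,
    zones = as.list(config$zones),
    sim = unclass(config$sim),
    geometry = unclass(config$geometry),
    cleaning = config$cleaning,
    protocol = unclass(config$protocol)
  )
}

#' Run the full pipeline: simulate, clean, detect, network, infer
#'
#' Orchestrates the stages end to end with file-based handoffs so each
#' stage's artifact can be inspected or re-run in isolation:
#' `positions_raw.csv` (simulated + artifacts), `positions_clean.csv`,
#' `cleaning_log.csv`, one `matrix_day<k>_<zone>.csv` per day and zone,
#' `edges.csv`, `measures_nodes.csv`, `measures_networks.csv`,
#' `stats_report.csv` and `manifest.json` (config echo, seeds and a hash
#' of the written config). All randomness derives from the master seed,
#' so a rerun with the same config is byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory artifacts (`sim`, `clean`,
#'   `matrices`, `measures`, `stats`, `manifest`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  message("[simulate] ", config$sim$n_cows, " cows x ", config$sim$n_days,
          " days")
  sim <- step("simulate", simulate_herd(config$sim, config$geometry))
  raw <- step("simulate", inject_artifacts(sim$positions, config$sim,
                                           config$geometry))
  write_positions(raw, file.path(out_dir, "positions_raw.csv"))
  utils::write.csv(sim$attributes, file.path(out_dir, "attributes.csv"),
                   row.names = FALSE)
  write_matrix(sim$truth$affinity, file.path(out_dir, "affinity.csv"))
  if (!is.null(sim$truth$intervals))
    utils::write.csv(sim$truth$intervals,
                     file.path(out_dir, "truth_intervals.csv"),
                     row.names = FALSE)

  clean <- step("clean", clean_pipeline(raw, config$geometry, config$cleaning))
  for (i in seq_len(nrow(clean$stages)))
    message(sprintf("[clean] %s, removed_count=%d, removed_fraction=%.4f",
                    clean$stages$stage[i], clean$stages$removed_count[i],
                    clean$stages$removed_fraction[i]))
  write_positions(clean$positions, file.path(out_dir, "positions_clean.csv"))
  utils::write.csv(clean$stages, file.path(out_dir, "cleaning_log.csv"),
                   row.names = FALSE)

  roster <- sort(unique(sim$positions$animal_id))
  days <- seq_len(config$sim$n_days)
  matrices <- list()
  for (zone in config$zones) {
    for (day in days) {
      M <- step("detect", daily_interaction_matrix(
        clean$positions, config$geometry, zone, config$protocol, day,
        roster = roster))
      key <- sprintf("day%02d_%s", day, zone)
      matrices[[key]] <- M
      write_matrix(M, file.path(out_dir, paste0("matrix_", key, ".csv")))
    }
  }
  utils::write.csv(edge_list(matrices), file.path(out_dir, "edges.csv"),
                   row.names = FALSE)

  node_rows <- list(); net_rows <- list()
  for (key in names(matrices)) {
    M <- matrices[[key]]
    meas <- step("networks", network_measures(M))
    nd <- meas$nodes
    nd$day_index <- attr(M, "day_index"); nd$zone <- attr(M, "zone")
    node_rows[[key]] <- nd
    net_rows[[key]] <- data.frame(
      day_index = attr(M, "day_index"), zone = attr(M, "zone"),
      edge_density = meas$edge_density,
      component_count = meas$component_count, stringsAsFactors = FALSE)
  }
  measures <- list(nodes = do.call(rbind, node_rows),
                   networks = do.call(rbind, net_rows))
  utils::write.csv(measures$nodes,
                   file.path(out_dir, "measures_nodes.csv"), row.names = FALSE)
  utils::write.csv(measures$networks,
                   file.path(out_dir, "measures_networks.csv"),
                   row.names = FALSE)

  stats_rows <- step("stats", run_inference(config, matrices, sim, roster))
  utils::write.csv(stats_rows, file.path(out_dir, "stats_report.csv"),
                   row.names = FALSE)

  cfg_list <- run_config_to_list(config)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg_list, cfg_path)
  manifest <- list(
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stage_seeds = list(simulate = config$seed,
                       artifacts = config$seed + 404L,
                       stats = config$seed + 1000L),
    n_matrices = length(matrices),
    matrices = names(matrices),
    files = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, raw = raw, clean = clean, matrices = matrices,
                 measures = measures, stats = stats_rows,
                 manifest = manifest))
}

# inference battery over the run's matrices; one flat report row per test
run_inference <- function(config, matrices, sim, roster) {
  q <- config$q
  seed0 <- config$seed + 1000L
  days <- seq_len(config$sim$n_days)
  n_days <- length(days)
  rows <- list()
  add <- function(test, zone, day, stat, p_raw, m) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, zone = zone, day_block = day, statistic = stat,
      p_raw = p_raw, m = m, p_adjusted = bonferroni(p_raw, m), q = q,
      seed = seed0, stringsAsFactors = FALSE)
  }
  attrs <- sim$attributes
  for (zone in config$zones) {
    keys <- sprintf("day%02d_%s", days, zone)
    zmats <- matrices[keys]
    totals <- vapply(zmats, function(M) {
      rowSums(M, na.rm = TRUE)[roster]
    }, numeric(length(roster)))
    # inter-individual and between-day variation in daily interactions
    kw1 <- kw_permutation_test(totals, "inter_individual", q = q,
                               seed = seed0 + 1L)
    add("kw_inter_individual", zone, NA, kw1$t_o, kw1$p, length(config$zones))
    if (n_days >= 2) {
      kw2 <- kw_permutation_test(totals, "between_days", q = q,
                                 seed = seed0 + 2L)
      add("kw_between_days", zone, NA, kw2$t_o, kw2$p, length(config$zones))
    }
    # social differentiation per day
    for (d in days) {
      sd_res <- social_differentiation(zmats[[sprintf("day%02d_%s", d, zone)]],
                                       q = q, seed = seed0 + 10L + d)
      add("social_differentiation", zone, d, sd_res$S, sd_res$p, n_days)
    }
    # temporal block comparison
    if (n_days >= 2 * config$block_days) {
      tb <- temporal_block_comparison(zmats, config$block_days, q = q,
                                      seed = seed0 + 100L)
      for (k in seq_len(nrow(tb)))
        add("mantel_temporal", zone, tb$block_a[k], tb$R_s[k], tb$p_raw[k],
            tb$m[k])
    }
    # assortment by attributes, per day
    for (field in c("parity", "days_in_milk", "lameness")) {
      adm <- tryCatch(
        suppressWarnings(attribute_difference_matrix(attrs, field)),
        error = function(e) NULL)
      if (is.null(adm)) next
      if (length(unique(adm[upper.tri(adm)])) < 2) next
      for (d in days) {
        M <- zmats[[sprintf("day%02d_%s", d, zone)]]
        at <- tryCatch(
          assortment_test(M, adm, q = q, seed = seed0 + 200L + d),
          error = function(e) NULL)
        if (is.null(at)) next
        add(paste0("assortment_", field), zone, d, at$R_s, at$p, n_days)
      }
    }
    # lame vs non-lame comparisons on per-cow means
    cls <- attrs$lameness_class[match(roster, attrs$animal_id)]
    use <- cls %in% c("lame", "non_lame")
    if (sum(cls[use] == "lame") >= 2 && sum(cls[use] == "non_lame") >= 2) {
      mean_di <- rowMeans(totals)[use]
      wt <- wilcoxon_permutation_test(mean_di, cls[use], q = q,
                                      seed = seed0 + 300L)
      add("wilcoxon_lameness_daily_interactions", zone, NA, wt$W, wt$p, 3)
      nn <- length(roster)
      deg <- vapply(zmats, function(M) as.numeric(degree_and_clustering(M)$degree),
                    numeric(nn))
      cc <- vapply(zmats, function(M) degree_and_clustering(M)$clustering,
                   numeric(nn))
      wd <- wilcoxon_permutation_test(rowMeans(as.matrix(deg))[use], cls[use],
                                      q = q, seed = seed0 + 301L)
      add("wilcoxon_lameness_degree", zone, NA, wd$W, wd$p, 3)
      wc <- wilcoxon_permutation_test(rowMeans(as.matrix(cc))[use], cls[use],
                                      q = q, seed = seed0 + 302L)
      add("wilcoxon_lameness_clustering", zone, NA, wc$W, wc$p, 3)
    }
  }
  do.call(rbind, rows)
}
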