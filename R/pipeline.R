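#' Read a run configuration from JSON
#'
#' The configuration names the input files (one aligned FASTA per locus,
#' a manifest TSV), analysis parameters and the named strain groups to
#' test; see [run_full_analysis()] for the recognised fields.
#'
#' @param path JSON file.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# internal: stage wrapper -- abort with a stage-named message
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full multilocus analysis pipeline
#'
#' Executes, in order: data assembly, optional gap-column filtering,
#' concatenation, per-locus and combined NJ gene trees with bootstrap
#' supports, genealogical concordance species recognition, the three
#' recombination tests (Phi, IA, PHT) for each configured strain group,
#' border scans, and per-subclade diversity plus pairwise FST.  Each
#' stage's tabular output is written as TSV and the full results as JSON
#' (when `out_dir` is given); partial outputs are retained on failure.
#' Every stochastic step derives its seed from `config$seed` and records
#' it in its result.
#'
#' @param config list (or path to a JSON file readable by
#'   [read_run_config()]) with fields: `fasta` (named vector/list of
#'   per-locus FASTA paths) and `manifest` (TSV path), or a ready
#'   `dataset`; optional `max_gap_fraction`, `support_threshold` (0.95),
#'   `bootstrap` (100), `alpha` (0.05), `window_w` (100),
#'   `n_permutations` (1000), `pht_replicates` (1000), `seed` (1),
#'   `groups` (named list of strain-id vectors), `scans` (list of
#'   `list(name, focal, controls)`), `fst_pairs` (list of subclade label
#'   pairs; default all pairs).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with `dataset`, `concat`, `trees`, `gcpsr`, `group_tests`,
#'   `scans`, `popstats`, `fst`, and `report` (from [make_report()]).
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  seed <- config$seed %||% 1L
  alpha <- config$alpha %||% 0.05
  supp_thr <- config$support_threshold %||% 0.95
  bootstrap <- config$bootstrap %||% 100L
  n_perm <- config$n_permutations %||% 1000L
  pht_reps <- config$pht_replicates %||% 1000L
  window_w <- config$window_w %||% 100L
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  emit <- function(name, tab) {
    if (!is.null(out_dir) && is.data.frame(tab)) {
      write.table(tab, file.path(out_dir, paste0(name, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  dataset <- run_stage("assemble", {
    if (!is.null(config$dataset)) config$dataset
    else {
      manifest <- read_strain_manifest(config$manifest)
      alns <- lapply(names(config$fasta), function(nm)
        read_fasta_alignment(config$fasta[[nm]], nm))
      names(alns) <- names(config$fasta)
      assemble_dataset(manifest, alns,
                       policy = config$policy %||% "intersect")
    }
  })
  ids <- dataset$manifest$strain_id
  for (g in config$groups) {
    bad <- setdiff(unlist(g), ids)
    if (length(bad)) stop("stage 'config' failed: unknown strain ids: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(config$max_gap_fraction)) {
    dataset <- run_stage("filter", {
      loci <- lapply(dataset$loci, filter_columns,
                     max_gap_fraction = config$max_gap_fraction)
      structure(list(loci = loci, manifest = dataset$manifest),
                class = "multilocus_dataset")
    })
  }
  conc <- run_stage("concatenate", concatenate(dataset))
  emit("partition", conc$partition)

  trees <- run_stage("gene_trees", {
    out <- lapply(seq_along(dataset$loci), function(i) {
      gene_tree(dataset$loci[[i]], bootstrap = bootstrap, seed = seed + i)
    })
    names(out) <- names(dataset$loci)
    out$combined <- gene_tree(conc$alignment, bootstrap = bootstrap,
                              seed = seed + length(out) + 1L)
    out
  })
  if (!is.null(out_dir)) {
    for (nm in names(trees)) {
      write_gene_tree(trees[[nm]], file.path(out_dir, paste0(nm, ".nwk")))
    }
  }

  gcpsr <- run_stage("gcpsr", {
    tables <- lapply(setdiff(names(trees), "combined"), function(nm)
      extract_clades(trees[[nm]], supp_thr, nm))
    combined_tab <- extract_clades(trees$combined, supp_thr, "combined")
    recognize_species(tables, candidates = combined_tab,
                      support_threshold = supp_thr)
  })
  emit("gcpsr", gcpsr)

  groups <- config$groups %||%
    list(all = ids)
  group_tests <- run_stage("recombination_tests", {
    lapply(seq_along(groups), function(gi) {
      g <- groups[[gi]]
      sub <- subset_dataset(dataset, g)
      subc <- concatenate(sub)
      phi <- tryCatch(
        phi_test(subc$alignment, window_w = window_w,
                 n_permutations = n_perm, seed = seed + 100L + gi),
        phi_not_computable = function(e) NULL)
      ia <- tryCatch(
        index_of_association(sub, n_permutations = min(n_perm, 999L),
                             seed = seed + 200L + gi),
        error = function(e) NULL)
      pht <- if (length(g) >= 4L) {
        pht_test(subc$alignment, subc$partition, n_replicates = pht_reps,
                 seed = seed + 300L + gi)
      }
      list(group = names(groups)[gi], phi = phi, ia = ia, pht = pht)
    })
  })

  scans <- run_stage("border_scans", {
    lapply(seq_along(config$scans), function(si) {
      sc <- config$scans[[si]]
      res <- scan_borders(dataset, trees$combined, sc$focal, sc$controls,
                          candidates = sc$candidates, alpha = alpha,
                          phi_opts = list(window_w = window_w,
                                          n_permutations = n_perm),
                          seed = seed + 400L + 50L * si)
      emit(paste0("scan_", sc$name %||% si), res$steps)
      res
    })
  })

  pops <- run_stage("popstats", {
    by_sub <- split(ids, dataset$manifest$subclade)
    by_sub <- by_sub[lengths(by_sub) >= 2L]
    stats <- lapply(by_sub, function(g) {
      diversity_stats(subset_alignment(conc$alignment, g))
    })
    tab <- data.frame(
      subclade = names(stats),
      n = vapply(stats, function(s) s$n, 0L),
      S = vapply(stats, function(s) s$S, 0L),
      pi = vapply(stats, function(s) s$pi, 0),
      theta_w = vapply(stats, function(s) s$theta_w, 0),
      tajima_d = vapply(stats, function(s) s$tajima_d, 0),
      rm = vapply(names(stats), function(nm)
        min_recombination_events(subset_alignment(conc$alignment,
                                                  by_sub[[nm]])), 0L),
      stringsAsFactors = FALSE, row.names = NULL)
    emit("popstats", tab)
    list(stats = stats, table = tab, groups = by_sub)
  })

  fst <- run_stage("fst", {
    by_sub <- pops$groups
    pairs <- config$fst_pairs %||% {
      nms <- names(by_sub)
      if (length(nms) >= 2L) combn(nms, 2L, simplify = FALSE) else list()
    }
    rows <- lapply(pairs, function(pr) {
      g1 <- by_sub[[pr[[1L]]]]; g2 <- by_sub[[pr[[2L]]]]
      aln <- subset_alignment(conc$alignment, c(g1, g2))
      r <- tryCatch(
        hudson_fst(aln, rep(c(pr[[1L]], pr[[2L]]),
                            c(length(g1), length(g2)))),
        error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(pop1 = pr[[1L]], pop2 = pr[[2L]], hw = r$hw, hb = r$hb,
                 fst = r$fst, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    emit("fst", tab)
    tab
  })

  results <- list(dataset = dataset, concat = conc, trees = trees,
                  gcpsr = gcpsr, group_tests = group_tests, scans = scans,
                  popstats = pops$table, fst = fst, seed = seed,
                  alpha = alpha)
  results$report <- make_report(results)
  emit("summary", results$report)
  if (!is.null(out_dir)) {
    keep <- results[c("gcpsr", "popstats", "fst", "seed", "alpha")]
    keep$group_tests <- lapply(group_tests, function(gt) {
      lapply(gt, function(x) if (is.list(x))
        x[!vapply(x, is.function, NA)] else x)
    })
    keep$report <- results$report
    jsonlite::write_json(keep, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
  }
  results
}

#' Summarise pipeline results as one table
#'
#' One row per test and group: statistic, p-value, decision at `alpha`,
#' and the parameters used; rows are sorted by stage then group name.
#'
#' @param results the list returned by [run_full_analysis()] (or a subset
#'   with `group_tests` / `scans` / `alpha`).
#' @return a data.frame.
#' @export
make_report <- function(results) {
  alpha <- results$alpha %||% 0.05
  rows <- list()
  for (gt in results$group_tests %||% list()) {
    if (!is.null(gt$phi)) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = "phi", group = gt$group, statistic = gt$phi$phi,
        p = gt$phi$p_permutation,
        decision = if (gt$phi$p_permutation < alpha) "recombination"
                   else "no recombination",
        params = paste0("w=", gt$phi$window_w, ";perm=",
                        gt$phi$n_permutations, ";seed=", gt$phi$seed),
        stringsAsFactors = FALSE)
    }
    if (!is.null(gt$ia)) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = "ia", group = gt$group, statistic = gt$ia$ia,
        p = gt$ia$p_permutation,
        decision = gt$ia$heuristic_reading,
        params = paste0("perm=", gt$ia$n_permutations, ";seed=",
                        gt$ia$seed),
        stringsAsFactors = FALSE)
    }
    if (!is.null(gt$pht)) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = "pht", group = gt$group, statistic = gt$pht$t_obs,
        p = gt$pht$p_value,
        decision = if (gt$pht$p_value < alpha) "incongruence (recombination)"
                   else "congruent (clonal)",
        params = paste0("reps=", gt$pht$n_replicates, ";seed=",
                        gt$pht$seed),
        stringsAsFactors = FALSE)
    }
  }
  for (si in seq_along(results$scans %||% list())) {
    sc <- results$scans[[si]]
    rows[[length(rows) + 1L]] <- data.frame(
      stage = "scan", group = paste0("scan", si),
      statistic = sum(sc$steps$triggered), p = sc$baseline$phi_p,
      decision = paste0("recombining population of ",
                        length(sc$recombining_population)),
      params = paste0("alpha=", sc$alpha, ";mode=", sc$mode, ";seed=",
                      sc$seed),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(stage = character(0), group = character(0),
                      statistic = numeric(0), p = numeric(0),
                      decision = character(0), params = character(0)))
  }
  out[order(out$stage, out$group), , drop = FALSE]
}
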