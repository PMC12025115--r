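#' Run the full compositional clustering analysis
#'
#' Orchestrates the whole workflow on one composition table: amalgamate the
#' trace elements, close to 100, delta-replace residual zeros, compute
#' weighted log-ratio distances, Ward-cluster, cut at `k` (or select k by
#' silhouette when `k = NULL`), summarise every cluster (centers, total
#' variances, variation matrices, ratio tables), run the global ILR MANOVA
#' and all pairwise Hotelling tests, and write every product as plain-text
#' files (CSV / Newick) plus a run log. Re-running with the same inputs and
#' seed is bit-identical.
#'
#' @param data A composition table (tibble or path to a CSV readable by
#'   [read_composition_csv()]).
#' @param output_dir Directory for the report bundle (created if absent).
#' @param parts Part columns of the raw table.
#' @param trace_parts Parts amalgamated into `"Traces"` before analysis.
#' @param k Number of clusters; `NULL` selects k by silhouette over
#'   `k_range`.
#' @param k_range Candidate k values when `k` is `NULL`.
#' @param weighting `"column_means"` (weighted log-ratio metric, default) or
#'   `"uniform"` (classic Aitchison).
#' @param test_mode `"parametric"` or `"permutation"`.
#' @param n_perm Permutations for permutation mode.
#' @param seed Integer seed; mandatory when `test_mode = "permutation"`.
#' @param delta Zero-replacement value (percent).
#' @param denominator Variance denominator convention.
#' @return Invisibly, a list: `data` (analysed table with `cluster`),
#'   `tree`, `newick`, `assignments`, `summaries`, `centers`, `ratios`,
#'   `global_test`, `pairwise_tests`, `k`, `k_selection`, `weights`, `files`.
#' @export
run_full_analysis <- function(data, output_dir,
                              parts = c("C", "O", "Ca", "Mg", "Cl", "F", "P"),
                              trace_parts = c("Cl", "F", "P"),
                              k = NULL, k_range = 2:8,
                              weighting = c("column_means", "uniform"),
                              test_mode = c("parametric", "permutation"),
                              n_perm = 9999, seed = NULL, delta = 0.005,
                              denominator = c("n-1", "n")) {
  weighting <- match.arg(weighting)
  test_mode <- match.arg(test_mode)
  denominator <- match.arg(denominator)
  if (test_mode == "permutation" && is.null(seed)) {
    abort("Permutation tests enabled but no seed given: set `seed`.",
          class = "spicoda_validation_error")
  }
  if (is.character(data) && length(data) == 1) {
    data <- read_composition_csv(data, parts)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)),
            class = "spicoda_stage_error")
    })
  }
  tab <- stage("amalgamate", {
    out <- data
    present <- intersect(trace_parts, parts)
    if (length(present) > 0 && length(present) < length(parts)) {
      out <- amalgamate(out, present, "Traces", parts)
    }
    out
  })
  aparts <- c(setdiff(parts, trace_parts),
              if (length(intersect(trace_parts, parts)) > 0) "Traces")
  tab <- stage("close", close_composition(tab, aparts, kappa = 100))
  tab <- stage("zero_replacement",
               replace_zeros(tab, aparts, delta = delta, quiet = TRUE))
  w <- if (weighting == "column_means") part_weights(tab, aparts) else NULL
  d <- stage("distances", pairwise_distances(tab, aparts, w))
  tree <- stage("clustering", ward_linkage(d))
  ksel <- NULL
  if (is.null(k)) {
    ksel <- stage("k_selection", select_k(tree, d, k_range, "silhouette"))
    k <- ksel$best_k
  }
  assignments <- stage("cut", cut_tree(tree, k))
  tab$cluster <- assignments$cluster[match(.sample_ids(tab),
                                           assignments$sample_id)]
  summaries <- stage("summaries",
                     summarize_clusters(tab, "cluster", aparts,
                                        denominator = denominator))
  centers <- center_table(summaries)
  ratios <- ratio_summary(tab, "cluster", aparts)
  fit <- stage("ilr_model", fit_ilr_model(tab, "cluster", aparts))
  gt <- stage("global_test", global_test(fit, test_mode, n_perm, seed))
  pw <- stage("pairwise_tests",
              pairwise_tests(fit, "holm", test_mode, n_perm, seed))
  newick <- export_dendrogram(tree)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    assignments = file.path(output_dir, "cluster_assignments.csv"),
    centers = file.path(output_dir, "cluster_centers.csv"),
    ratios = file.path(output_dir, "ratio_summary.csv"),
    variation = file.path(output_dir, "variation_matrices.csv"),
    tests = file.path(output_dir, "test_results.csv"),
    dendrogram = file.path(output_dir, "dendrogram.nwk"),
    data = file.path(output_dir, "analyzed_table.csv"),
    log = file.path(output_dir, "run_log.txt"))
  readr::write_csv(dplyr::mutate(assignments,
                                 cluster = as.character(.data$cluster)),
                   files$assignments, progress = FALSE)
  readr::write_csv(centers, files$centers, progress = FALSE)
  readr::write_csv(ratios, files$ratios, progress = FALSE)
  vm <- purrr::map_dfr(summaries, function(s) {
    m <- s$variation
    dplyr::bind_cols(tibble(cluster = s$name, part = rownames(m)),
                     as_tibble(as.data.frame(m)))
  })
  readr::write_csv(vm, files$variation, progress = FALSE)
  tests <- dplyr::bind_rows(
    dplyr::mutate(gt, group1 = "(all)", group2 = "(all)", p_adjusted = NA_real_),
    dplyr::mutate(pw, statistic_name = "Hotelling T2"))
  readr::write_csv(tests, files$tests, progress = FALSE)
  writeLines(newick, files$dendrogram)
  write_composition_csv(dplyr::mutate(tab,
                                      cluster = as.character(.data$cluster)),
                        files$data, aparts)
  log_lines <- c(
    paste0("spicoda ", as.character(utils::packageVersion("spicoda"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("samples: ", nrow(tab)),
    paste0("parts: ", paste(aparts, collapse = ",")),
    paste0("trace_parts: ", paste(trace_parts, collapse = ",")),
    paste0("weighting: ", weighting),
    if (!is.null(w)) paste0("weights: ",
                            paste(sprintf("%s=%.6f", names(w), w),
                                  collapse = ",")),
    paste0("variance_denominator: ", denominator),
    paste0("delta: ", delta),
    paste0("k: ", k, if (!is.null(ksel)) " (silhouette-selected)" else
             " (user-supplied)"),
    paste0("test_mode: ", test_mode),
    paste0("n_perm: ", if (test_mode == "permutation") n_perm else "NA"),
    paste0("seed: ", if (is.null(seed)) "NA" else seed))
  writeLines(log_lines, files$log)

  invisible(list(data = tab, tree = tree, newick = newick,
                 assignments = assignments, summaries = summaries,
                 centers = centers, ratios = ratios, global_test = gt,
                 pairwise_tests = pw, k = k, k_selection = ksel,
                 weights = w, files = files))
}

#' Run a simulation scenario and write its outputs
#'
#' Generates a synthetic composition table from a scenario (a YAML file path
#' or a list of [cluster_spec()] objects), writes the table in the standard
#' CSV schema plus a truth file of the generating cluster labels for
#' recovery scoring.
#'
#' @param scenario YAML path or list of `cluster_spec` objects.
#' @param output_dir Output directory (created if absent).
#' @param seed Integer seed; overrides the scenario file's seed.
#' @param prep `prep` metadata value; overrides the scenario file's.
#' @return Invisibly, a list: `data`, `files`.
#' @export
run_simulation <- function(scenario, output_dir, seed = NULL, prep = NULL) {
  if (is.character(scenario) && length(scenario) == 1) {
    sc <- read_scenario(scenario)
    specs <- sc$specs
    seed <- seed %||% sc$seed
    prep <- prep %||% sc$prep
  } else {
    specs <- scenario
    prep <- prep %||% "section"
  }
  if (is.null(seed)) abort("No seed given (neither argument nor scenario).",
                           class = "spicoda_validation_error")
  data <- generate_clusters(specs, seed = seed, prep = prep)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(data = file.path(output_dir, "synthetic_compositions.csv"),
                truth = file.path(output_dir, "true_clusters.csv"))
  readr::write_csv(dplyr::select(data, -"true_cluster"), files$data,
                   progress = FALSE)
  readr::write_csv(dplyr::select(data, "sample_id", "true_cluster"),
                   files$truth, progress = FALSE)
  invisible(list(data = data, files = files))
}
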