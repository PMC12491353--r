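# --- end-to-end pipeline ---------------------------------------------------

#' Run the full Y-STR analysis workflow
#'
#' Wires the package's stages in the usual order — forensic summary,
#' allele frequencies, distance matrices (pairwise differences and R_ST),
#' MDS, dendrogram, median-joining network, allelic-richness rarefaction,
#' and (when a Q matrix or a haplogroup reference is supplied) ancestry
#' variability and haplogroup prediction — writing one artifact per stage
#' plus a JSON manifest with the effective configuration, seeds and file
#' hashes. Deterministic stages reproduce identical hashes on rerun.
#' Multi-population stages are skipped automatically (and noted in the
#' manifest) when the input has a single population.
#'
#' @param input a `hap_tbl` or path readable by [read_haplotypes()].
#' @param out_dir output directory (created if needed).
#' @param q optional Q-matrix tibble (see [read_qmatrix()]) or path.
#' @param reference optional haplogroup reference table (a `hap_tbl` with a
#'   `haplogroup` column) for prediction.
#' @param include_dys385 include DYS385 in distance computations.
#' @param dys389ii `"raw"` or `"encoded"` DYS389II in distances.
#' @param round_microvariants round alleles before distances.
#' @param mds_k,nonmetric MDS dimension and flavor.
#' @param linkage,tree_k dendrogram agglomeration and cluster cut (cut
#'   skipped if `tree_k` exceeds the number of populations).
#' @param epsilon median-joining relaxation parameter.
#' @param bootstrap,seed FSTruct bootstrap replicates and the seed recorded
#'   for every stochastic stage.
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(input, out_dir,
                         q = NULL, reference = NULL,
                         include_dys385 = TRUE, dys389ii = "raw",
                         round_microvariants = FALSE,
                         mds_k = 2, nonmetric = FALSE,
                         linkage = "average", tree_k = NULL,
                         epsilon = 0, bootstrap = 100, seed = 1) {
  tbl <- if (is.character(input)) read_haplotypes(input) else input
  if (is.character(q)) q <- read_qmatrix(q)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  add <- function(stage, path) {
    artifacts[[length(artifacts) + 1]] <<- list(stage = stage,
                                                file = basename(path))
  }
  pth <- function(f) file.path(out_dir, f)

  # forensic summary
  fs <- forensic_summary(tbl)
  readr::write_csv(tidy(fs), pth("summary_per_locus.csv"))
  jsonlite::write_json(as.list(glance(fs)), pth("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  add("summary", pth("summary_per_locus.csv"))
  add("summary", pth("summary.json"))

  readr::write_csv(allele_frequencies(tbl), pth("allele_frequencies.csv"))
  add("frequencies", pth("allele_frequencies.csv"))

  pops <- unique(tbl$population)
  multi_pop <- length(pops) >= 2 &&
    all(table(tbl$population) >= 2)
  if (multi_pop) {
    R <- rst_matrix(tbl, include_multi_copy = include_dys385,
                    dys389ii = dys389ii,
                    round_microvariants = round_microvariants)
    readr::write_csv(as_tibble(R, rownames = "population"), pth("rst_matrix.csv"))
    add("distance", pth("rst_matrix.csv"))
    pd <- pairwise_differences(tbl, include_multi_copy = include_dys385,
                               dys389ii = dys389ii,
                               round_microvariants = round_microvariants)
    readr::write_csv(tidy(pd), pth("pairwise_differences.csv"))
    readr::write_csv(pd$pi_x, pth("within_differences.csv"))
    add("distance", pth("pairwise_differences.csv"))
    add("distance", pth("within_differences.csv"))

    if (length(pops) >= 4) {
      D <- pmax(R, 0)
      mds <- if (nonmetric) nonmetric_mds(D, k = mds_k) else classical_mds(D, k = mds_k)
      readr::write_csv(tidy(mds), pth("mds_coordinates.csv"))
      jsonlite::write_json(as.list(glance(mds)), pth("mds.json"),
                           auto_unbox = TRUE, digits = NA)
      add("mds", pth("mds_coordinates.csv"))
      add("mds", pth("mds.json"))
    }
    if (length(pops) >= 3) {
      dend <- upgma(pmax(R, 0), linkage = linkage)
      write_newick(dend, pth("dendrogram.nwk"))
      add("tree", pth("dendrogram.nwk"))
      kk <- tree_k %||% min(8, length(pops))
      if (kk <= length(pops)) {
        readr::write_csv(cut_dendrogram(dend, kk), pth("clusters.csv"))
        add("tree", pth("clusters.csv"))
      }
    }
    rich <- richness_profile(tbl)
    readr::write_csv(as_tibble(as.data.frame(rich)), pth("richness.csv"))
    add("richness", pth("richness.csv"))
  }

  net <- median_joining(tbl, epsilon = epsilon)
  export_network(net, pth("network.graphml"), "graphml")
  readr::write_csv(select(net$nodes, -"members"), pth("network_nodes.csv"))
  add("network", pth("network.graphml"))
  add("network", pth("network_nodes.csv"))

  if (!is.null(q)) {
    fr <- fstruct(q, B = bootstrap, seed = seed)
    readr::write_csv(as_tibble(as.data.frame(fr))[, setdiff(names(fr), "boot")],
                     pth("fstruct.csv"))
    readr::write_csv(tidy(fr), pth("fstruct_replicates.csv"))
    add("fstruct", pth("fstruct.csv"))
    add("fstruct", pth("fstruct_replicates.csv"))
  }
  if (!is.null(reference)) {
    model <- fit_haplogroup_model(reference)
    readr::write_csv(predict_haplogroup(tbl, model), pth("haplogroups.csv"))
    add("predict", pth("haplogroups.csv"))
  }

  files <- vapply(artifacts, `[[`, character(1), "file")
  manifest <- list(
    package = "ystrpop",
    version = as.character(utils::packageVersion("ystrpop")),
    seed = seed,
    switches = list(include_dys385 = include_dys385, dys389ii = dys389ii,
                    round_microvariants = round_microvariants,
                    mds_k = mds_k, nonmetric = nonmetric, linkage = linkage,
                    epsilon = epsilon, bootstrap = bootstrap),
    artifacts = lapply(artifacts, function(a) {
      p <- file.path(out_dir, a$file)
      list(stage = a$stage, file = a$file,
           md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
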