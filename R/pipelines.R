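# End-to-end workflows chaining the modules; these back the command-line
# entry point (inst/cli/oleadiv) and are convenient from the console.

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Genetic analysis workflow
#'
#' Per-locus diversity summary (with HWE), clone/genet identification with
#' Pgen, the Dice-Sorensen/Ward dendrogram, and (when an admixture Q-matrix
#' is supplied) the hard-assignment partition and its ARI against the
#' dendrogram cut.
#'
#' @param g a [genotype_table()].
#' @param k clusters to cut the dendrogram into (default 3).
#' @param n_perm HWE permutations.
#' @param seed seed for permutation tests.
#' @param q_matrix optional [read_q_matrix()] result.
#' @param allele_tolerance_bp clone-matching tolerance (bp).
#' @param out_dir optional output directory: writes `locus_summary.tsv`,
#'   `clones.csv`, `dendrogram.nwk`, `genetics.json`.
#' @return list with `summary`, `clones`, `pgen`, `tree`, `partition`, and
#'   optionally `ari_vs_q`.
#' @export
run_genetics <- function(g, k = 3, n_perm = 10000, seed = NULL,
                         q_matrix = NULL, allele_tolerance_bp = 0,
                         out_dir = NULL) {
  summary <- locus_summary(g, n_perm = n_perm, seed = seed)
  clones <- find_clones(g, allele_tolerance_bp = allele_tolerance_bp)
  pg <- vapply(g$sample_ids, function(id) pgen(g, id)$pgen, numeric(1))
  m <- allele_matrix(g)
  d <- genetic_distance_matrix(m)
  tree <- ward_tree(d)
  part <- cut_tree(tree, k)
  out <- list(summary = summary, clones = clones, pgen = pg, tree = tree,
              partition = part, n_genotypes = attr(clones, "n_genotypes"))
  if (!is.null(q_matrix)) {
    qp <- hard_assignment(q_matrix)
    out$q_partition <- qp
    out$ari_vs_q <- adjusted_rand_index(part, qp)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary, file.path(out_dir, "locus_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(sample_id = names(clones),
                                genotype_group = as.integer(clones),
                                pgen = pg[names(clones)]),
                     file.path(out_dir, "clones.csv"), row.names = FALSE)
    write_newick(tree, file.path(out_dir, "dendrogram.nwk"))
    write_json_report(list(seed = seed, n_perm = n_perm, k = k,
                           n_genotypes = out$n_genotypes,
                           ari_vs_q = out$ari_vs_q),
                      file.path(out_dir, "genetics.json"))
  }
  out
}

#' Quantitative trait workflow
#'
#' Kruskal-Wallis tests with Siegel-Castellan post-hoc grids per variable,
#' the MUFA/PUFA ratio (fatty-acid input), PCA, gap-statistic model
#' selection, PAM at the chosen k with silhouette diagnostics, and the ARI
#' of the PAM partition against the collection sites.
#'
#' @param q a [quantitative_matrix()].
#' @param sites site labels aligned with `rownames(q)`.
#' @param is_fatty treat `q` as fatty-acid percentages (adds MUFA/PUFA)?
#' @param alpha significance level.
#' @param k_max,B gap-statistic controls.
#' @param seed seed for the gap reference draws.
#' @param out_dir optional output directory (`traits.json`,
#'   `cluster_membership.csv`).
#' @param samples optional [sample_table()] for GeoJSON export of
#'   cluster-coloured points.
#' @return list with `kw`, `mufa_pufa` (or NULL), `pca`, `gap`, `pam`,
#'   `silhouette`, `ari_vs_sites`, `chosen_k`.
#' @export
run_traits <- function(q, sites, is_fatty = TRUE, alpha = 0.05, k_max = 8,
                       B = 50, seed = NULL, out_dir = NULL, samples = NULL) {
  stopifnot(length(sites) == nrow(q))
  kw <- group_comparison_report(q, sites, alpha = alpha)
  ratio <- NULL
  if (is_fatty) {
    ratio <- mufa_pufa_ratio(q)
    kw_ratio <- kruskal_wallis(ratio[is.finite(ratio)],
                               sites[is.finite(ratio)])
    kw$tests <- rbind(kw$tests,
                      data.frame(variable = "MUFA/PUFA", H = kw_ratio$H,
                                 df = kw_ratio$df, p = kw_ratio$p,
                                 significant = kw_ratio$p < alpha))
    kw$posthoc[["MUFA/PUFA"]] <-
      kw_posthoc_siegel_castellan(ratio[is.finite(ratio)],
                                  sites[is.finite(ratio)], alpha = alpha)
  }
  pc <- pca(q, scale. = TRUE)
  scores2 <- pc$scores[, 1:2, drop = FALSE]
  gap <- gap_statistic(scores2, k_max = k_max, B = B, seed = seed)
  k <- max(2L, attr(gap, "chosen_k"))
  pam_fit <- pam_cluster(scores2, k)
  d2 <- euclidean_matrix(scores2)
  sil <- silhouette_report(pam_fit$partition, d2)
  site_part <- stats::setNames(as.integer(factor(sites)), rownames(q))
  ari <- adjusted_rand_index(pam_fit$partition, site_part)
  out <- list(kw = kw, mufa_pufa = ratio, pca = pc, gap = gap,
              pam = pam_fit, silhouette = sil, ari_vs_sites = ari,
              chosen_k = attr(gap, "chosen_k"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(sample_id = names(pam_fit$partition),
                                site = sites,
                                cluster = as.integer(pam_fit$partition)),
                     file.path(out_dir, "cluster_membership.csv"),
                     row.names = FALSE)
    write_json_report(list(seed = seed, alpha = alpha, B = B,
                           chosen_k = attr(gap, "chosen_k"),
                           mean_silhouette = sil$mean,
                           ari_vs_sites = ari,
                           kw = kw$tests,
                           gap = as.data.frame(gap)),
                      file.path(out_dir, "traits.json"))
    if (!is.null(samples)) {
      write_points_geojson(samples, file.path(out_dir, "clusters.geojson"),
                           properties = data.frame(
                             cluster = as.integer(
                               pam_fit$partition[samples$sample_id])))
    }
  }
  out
}

#' Macro-descriptor integration workflow
#'
#' Builds the four descriptor distance matrices (geographic and
#' morphometric Euclidean, fatty-acid Canberra, SSR Dice-Sorensen) and runs
#' the Mantel test on all 6 unordered pairs, with an optional genets-only
#' subset (members of multilocus-genotype groups of at least
#' `min_clone_size` trees).
#'
#' @param samples a [sample_table()].
#' @param morpho,fatty [quantitative_matrix()] objects.
#' @param g a [genotype_table()].
#' @param n_perm Mantel permutations per pair.
#' @param seed base seed.
#' @param genets_only also compute the clone-subset table?
#' @param min_clone_size minimum clone-group size for the subset.
#' @param allele_tolerance_bp clone-matching tolerance in bp (somatic
#'   variants of one genet typically differ by 2-3 bp).
#' @param out_dir optional output directory (`mantel.tsv`, `mantel.json`).
#' @return list with `full` (6-pair data.frame), optionally `genets`, and
#'   `descriptors`.
#' @export
run_integration <- function(samples, morpho, fatty, g, n_perm = 10000,
                            seed = NULL, genets_only = FALSE,
                            min_clone_size = 4, allele_tolerance_bp = 0,
                            out_dir = NULL) {
  ids <- samples$sample_id
  if (!identical(rownames(morpho), ids) || !identical(rownames(fatty), ids) ||
      !identical(g$sample_ids, ids)) {
    stop_schema("samples misaligned across inputs")
  }
  geo <- euclidean_matrix(cbind(easting = samples$easting,
                                northing = samples$northing) |>
                            `rownames<-`(ids))
  dm <- euclidean_matrix(morpho)
  df <- canberra_matrix(fatty)
  dg <- genetic_distance_matrix(allele_matrix(g))
  ds <- descriptor_set(geo, dm, df, dg)
  out <- list(descriptors = ds,
              full = descriptor_correlations(ds, n_perm = n_perm,
                                             seed = seed))
  if (genets_only) {
    clones <- find_clones(g, allele_tolerance_bp = allele_tolerance_bp)
    sizes <- table(clones)
    keep <- names(clones)[clones %in%
                            as.integer(names(sizes)[sizes >= min_clone_size])]
    if (length(keep) >= 4L) {
      out$genets <- descriptor_correlations(
        ds, n_perm = n_perm,
        seed = if (is.null(seed)) NULL else seed + 100L, samples = keep)
      out$genet_samples <- keep
    } else {
      warning("fewer than 4 samples in clone groups; subset skipped")
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out$full, file.path(out_dir, "mantel.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_json_report(list(seed = seed, n_perm = n_perm, full = out$full,
                           genets = out$genets),
                      file.path(out_dir, "mantel.json"))
  }
  out
}
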