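#' Construct a sample table
#'
#' A sample table holds one row per tree: a unique identifier, the collection
#' site it belongs to, and projected (UTM) coordinates in metres, so that
#' geographic distances can be taken as plain Euclidean distances.
#'
#' @param df data.frame with columns `sample_id`, `site`, `easting`,
#'   `northing`.
#' @return data.frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  require_columns(df, c("sample_id", "site", "easting", "northing"),
                  "sample table")
  df$sample_id <- as.character(df$sample_id)
  df$site <- as.character(df$site)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L) {
    stop_schema("duplicated sample_id(s): %s", paste(dup, collapse = ", "))
  }
  if (!is.numeric(df$easting) || !is.numeric(df$northing) ||
      any(!is.finite(df$easting)) || any(!is.finite(df$northing))) {
    stop_schema("coordinates must be finite numbers")
  }
  if (any(table(df$site) < 1L)) stop_schema("every site needs >= 1 sample")
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from a delimited text file
#'
#' @param path file path; comma- and semicolon-separated files are
#'   auto-detected.
#' @param sep optional explicit separator.
#' @param col_map optional named character vector remapping the file's column
#'   headers onto the canonical names, e.g.
#'   `c(sample_id = "ID", site = "Area", easting = "X", northing = "Y")`.
#' @return a [sample_table()].
#' @export
read_sample_table <- function(path, sep = NULL, col_map = NULL) {
  df <- read_delim_file(path, sep)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  sample_table(df)
}

#' Write a sample table to CSV
#' @param x sample_table
#' @param path output file
#' @export
write_sample_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a diploid genotype table
#'
#' Stores two allele sizes (bp, positive integers) per sample and locus.
#' Allele pairs are normalised so that `a1 <= a2`; a call with either allele
#' missing is treated as missing for the whole locus (half-calls cannot be
#' distinguished from homozygotes on capillary traces).
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (samples x loci) of allele sizes; `NA` for
#'   missing.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(sample_ids, loci, a1, a2) {
  sample_ids <- as.character(sample_ids)
  loci <- as.character(loci)
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop_schema("duplicated sample_id(s): %s", paste(dup, collapse = ", "))
  }
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "double"; storage.mode(a2) <- "double"
  if (!all(dim(a1) == c(length(sample_ids), length(loci))) ||
      !all(dim(a2) == dim(a1))) {
    stop_schema("allele matrices must be samples x loci")
  }
  bad <- which((!is.na(a1) & (a1 <= 0 | a1 != round(a1))) |
               (!is.na(a2) & (a2 <= 0 | a2 != round(a2))))
  if (length(bad) > 0L) {
    stop_schema("allele sizes must be positive integers (first bad cell: %d)",
                bad[1])
  }
  # half-missing -> fully missing; then order each pair
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_real_; a2[miss] <- NA_real_
  swap <- !miss & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(sample_ids, loci)
  structure(list(sample_ids = sample_ids, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d loci (%d missing calls)\n",
              length(x$sample_ids), length(x$loci), sum(is.na(x$a1))))
  invisible(x)
}

#' Missing-call mask of a genotype table
#' @param g genotype_table
#' @return logical matrix (samples x loci), TRUE where the call is missing.
#' @export
missing_mask <- function(g) is.na(g$a1)

#' Read a genotype table
#'
#' The canonical layout is wide, GenAlEx-style: a `sample_id` column followed
#' by two columns per locus (headers `LOCUS_1`/`LOCUS_2`, `LOCUS`/`LOCUS.1`,
#' or the locus name repeated). A long layout
#' (`sample_id, locus, a1, a2`) is also accepted. Blank cells are missing.
#'
#' @param path file path.
#' @param sep optional separator override.
#' @param layout `"wide"` or `"long"`.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, sep = NULL, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  df <- read_delim_file(path, sep)
  require_columns(df, "sample_id", "genotype file")
  parse_allele <- function(v, cols) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad) > 0L) {
      stop_schema("non-integer allele size '%s' (column %s, row %d)",
                  v[bad[1]], cols, bad[1])
    }
    out[v %in% c("", NA)] <- NA_real_
    out
  }
  if (layout == "long") {
    require_columns(df, c("locus", "a1", "a2"), "long genotype file")
    ids <- unique(as.character(df$sample_id))
    loci <- unique(as.character(df$locus))
    a1 <- a2 <- matrix(NA_real_, length(ids), length(loci),
                       dimnames = list(ids, loci))
    i <- match(as.character(df$sample_id), ids)
    j <- match(as.character(df$locus), loci)
    a1[cbind(i, j)] <- parse_allele(as.character(df$a1), "a1")
    a2[cbind(i, j)] <- parse_allele(as.character(df$a2), "a2")
    return(genotype_table(ids, loci, a1, a2))
  }
  allele_cols <- setdiff(names(df), "sample_id")
  if (length(allele_cols) %% 2L != 0L) {
    stop_schema("wide genotype file needs two columns per locus")
  }
  first <- allele_cols[seq(1L, length(allele_cols), by = 2L)]
  loci <- sub("([._]1|\\.x)$", "", first)
  ids <- as.character(df$sample_id)
  a1 <- a2 <- matrix(NA_real_, length(ids), length(loci),
                     dimnames = list(ids, loci))
  for (k in seq_along(loci)) {
    c1 <- allele_cols[2L * k - 1L]; c2 <- allele_cols[2L * k]
    a1[, k] <- parse_allele(as.character(df[[c1]]), c1)
    a2[, k] <- parse_allele(as.character(df[[c2]]), c2)
  }
  genotype_table(ids, loci, a1, a2)
}

#' Write a genotype table in the wide two-columns-per-locus layout
#' @param g genotype_table
#' @param path output file
#' @export
write_genotypes <- function(g, path) {
  out <- data.frame(sample_id = g$sample_ids, stringsAsFactors = FALSE)
  for (k in seq_along(g$loci)) {
    out[[paste0(g$loci[k], "_1")]] <- g$a1[, k]
    out[[paste0(g$loci[k], "_2")]] <- g$a2[, k]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a quantitative trait matrix
#'
#' Samples x named continuous variables: morphometric means (olive weight in
#' g, major drupe axis in cm, leaf area in cm^2) or fatty-acid relative
#' abundances in percent.
#'
#' @param x numeric matrix or data.frame with sample ids as row names (or a
#'   `sample_id` column).
#' @param percent if TRUE the values are percentages and must lie in
#'   \[0, 100\].
#' @return numeric matrix of class `quant_matrix`.
#' @export
quantitative_matrix <- function(x, percent = FALSE) {
  if (is.data.frame(x)) {
    if ("sample_id" %in% names(x)) {
      rn <- as.character(x$sample_id)
      x <- x[, setdiff(names(x), "sample_id"), drop = FALSE]
      rownames(x) <- rn
    }
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stop_schema("quantitative values must be numeric")
  if (is.null(rownames(x))) stop_schema("sample ids (row names) required")
  if (anyDuplicated(colnames(x))) stop_schema("variable names must be unique")
  if (percent && any(x < 0 | x > 100, na.rm = TRUE)) {
    stop_schema("percentages must lie in [0, 100]")
  }
  structure(x, class = c("quant_matrix", class(x)), percent = percent)
}

#' Read a quantitative trait table (CSV, first column = sample id)
#' @param path file path
#' @param sep optional separator
#' @param percent see [quantitative_matrix()]
#' @export
read_quantitative <- function(path, sep = NULL, percent = FALSE) {
  df <- read_delim_file(path, sep)
  names(df)[1] <- "sample_id"
  quantitative_matrix(df, percent = percent)
}

#' Write a quantitative matrix to CSV
#' @param x quant_matrix
#' @param path output file
#' @export
write_quantitative <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average replicate measurements per tree
#'
#' Field campaigns measure ~20 leaves/drupes per tree; downstream analyses
#' use a single value per tree and variable, so replicates are reduced
#' (by their mean, by default).
#'
#' @param df data.frame with a `sample_id` column and numeric replicate
#'   columns (one row per replicate).
#' @param reducer function applied per sample and variable (default `mean`).
#' @return [quantitative_matrix()] with attribute `n_replicates` (samples x
#'   variables count matrix). Samples with zero replicates for some variable
#'   get `NA` there.
#' @export
aggregate_replicates <- function(df, reducer = mean) {
  require_columns(df, "sample_id", "replicate table")
  vars <- setdiff(names(df), "sample_id")
  if (length(vars) == 0L) stop_schema("no measurement columns")
  ids <- unique(as.character(df$sample_id))
  out <- matrix(NA_real_, length(ids), length(vars),
                dimnames = list(ids, vars))
  nrep <- matrix(0L, length(ids), length(vars), dimnames = dimnames(out))
  for (v in vars) {
    vals <- df[[v]]
    ok <- !is.na(vals)
    if (any(ok)) {
      agg <- tapply(vals[ok], as.character(df$sample_id)[ok], reducer)
      out[names(agg), v] <- as.numeric(agg)
      cnt <- tapply(vals[ok], as.character(df$sample_id)[ok], length)
      nrep[names(cnt), v] <- as.integer(cnt)
    }
  }
  res <- quantitative_matrix(out)
  attr(res, "n_replicates") <- nrep
  res
}

#' Construct a validated distance matrix
#'
#' @param m symmetric numeric matrix with zero diagonal, non-negative
#'   entries, and sample ids as dimnames.
#' @param metric tag: one of `"euclidean"`, `"canberra"`, `"dice_sorensen"`.
#' @return matrix of class `dist_matrix` with a `metric` attribute.
#' @export
dist_matrix <- function(m, metric = c("euclidean", "canberra",
                                      "dice_sorensen")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_schema("distance matrix must be square")
  if (is.null(rownames(m))) stop_schema("distance matrix needs sample ids")
  if (any(!is.finite(m))) stop_schema("distances must be finite")
  if (any(m < 0)) stop_schema("distances must be non-negative")
  if (max(abs(m - t(m))) > 1e-8) stop_schema("distance matrix not symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop_schema("diagonal must be zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  colnames(m) <- rownames(m)
  structure(m, class = c("dist_matrix", "matrix", "array"), metric = metric)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d samples\n", attr(x, "metric"), nrow(x)))
  invisible(x)
}

#' Coerce a dist_matrix to stats::dist
#' @param x dist_matrix
#' @export
as_dist <- function(x) stats::as.dist(unclass(x))

#' Export an agglomerative dendrogram as Newick
#'
#' Branch lengths follow the ultrametric convention: the leaf-to-root path
#' length equals half... specifically, every leaf sits at depth equal to half
#' the root merge height on each side, so a two-leaf tree merged at height h
#' becomes `(A:h/2,B:h/2);`.
#'
#' @param tree an `hclust` object (as returned by [ward_tree()]).
#' @param path output file.
#' @return the Newick string, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Write samples as GeoJSON points
#'
#' Minimal exporter for map overlays (one Point feature per sample with its
#' site and any extra properties, e.g. cluster membership). Coordinates are
#' written as given (projected metres); reproject beforehand if a viewer
#' expects longitude/latitude. Shapefile input/output is out of scope:
#' convert with e.g. `ogr2ogr -f GeoJSON out.geojson in.shp`.
#'
#' @param samples a [sample_table()].
#' @param path output file.
#' @param properties optional data.frame of extra per-sample properties.
#' @export
write_points_geojson <- function(samples, path, properties = NULL) {
  feats <- lapply(seq_len(nrow(samples)), function(i) {
    props <- list(sample_id = samples$sample_id[i], site = samples$site[i])
    if (!is.null(properties)) {
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    }
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(samples$easting[i],
                                         samples$northing[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
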