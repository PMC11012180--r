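#' Build a haploid genotype matrix from a variant table
#'
#' Restricts to gap-free biallelic encodings: rows whose column contains an
#' alignment gap in any sample are excluded (the gap rule), multiallelic rows
#' are split into one column per alternate allele, and entries are 0 (allele
#' differs from that alternate - reference or another alternate), 1 (carries
#' the alternate) or `NA` (missing `N`).
#'
#' @param vt A [call_variants()] result.
#' @param region Optional closed interval `c(start, end)` of rCRS positions.
#' @return Object of class `genotype_matrix`: list with `G` (samples x sites
#'   numeric matrix, colnames `position_alt`) and `sites` (`data.frame`:
#'   position, ref, alt).
#' @export
build_genotype_matrix <- function(vt, region = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  keep <- !vt$sites$has_gap
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] <= region[2])
    keep <- keep & vt$sites$position >= region[1] &
      vt$sites$position <= region[2]
  }
  idx <- which(keep)
  cols <- list()
  meta <- list()
  for (i in idx) {
    alts <- strsplit(vt$sites$alt[i], ",", fixed = TRUE)[[1]]
    col <- vt$calls[, i]
    for (a in alts) {
      g <- as.numeric(col == a)
      g[!col %in% c("A", "C", "G", "T")] <- NA
      cols[[paste0(vt$sites$position[i], "_", a)]] <- g
      meta[[length(meta) + 1L]] <- data.frame(
        position = vt$sites$position[i], ref = vt$sites$ref[i], alt = a,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cols)) {
    G <- matrix(numeric(0), nrow = nrow(vt$calls), ncol = 0,
                dimnames = list(rownames(vt$calls), NULL))
    sites <- data.frame(position = integer(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE)
  } else {
    G <- do.call(cbind, cols)
    rownames(G) <- rownames(vt$calls)
    sites <- do.call(rbind, meta)
  }
  structure(list(G = G, sites = sites), class = "genotype_matrix")
}

#' PCA of a haploid genotype matrix
#'
#' Missing entries are mean-imputed per column; columns are centred by allele
#' frequency and, under the default variance standardisation, scaled by
#' `sqrt(p * (1 - p))` with `p` the alternate-allele frequency (the scaling
#' used by standard population-genetics PCA tools); monomorphic columns are
#' dropped with a message. Scores come from the singular value decomposition;
#' each component's sign is fixed by making its largest-magnitude loading
#' positive, so results are reproducible.
#'
#' @param gm A [build_genotype_matrix()] result (or a plain numeric matrix).
#' @param k Number of components to return (default 2).
#' @param standardize `TRUE` for allele-frequency variance scaling, `FALSE`
#'   for centred-only PCA.
#' @return Object of class `pca_result`: list with `scores` (samples x k),
#'   `explained_variance` (k values, variance explained by each component),
#'   `explained_fraction`, `loadings`, `n_sites_used`.
#' @export
run_pca <- function(gm, k = 2L, standardize = TRUE) {
  G <- if (inherits(gm, "genotype_matrix")) gm$G else gm
  stopifnot(is.matrix(G))
  n <- nrow(G)
  if (n < 2) stop("need at least 2 samples")
  if (ncol(G) < 1) stop("empty genotype matrix: no sites after filtering")
  p <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- p[j]
  mono <- p <= 0 | p >= 1 | apply(G, 2, function(x) all(x == x[1]))
  if (any(mono)) {
    message("dropping ", sum(mono), " monomorphic column(s)")
    G <- G[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(G) == 0) {
    scores <- matrix(0, n, k, dimnames = list(rownames(G), paste0("PC", 1:k)))
    return(structure(list(scores = scores,
                          explained_variance = rep(0, k),
                          explained_fraction = rep(0, k),
                          loadings = NULL, n_sites_used = 0L),
                     class = "pca_result"))
  }
  X <- sweep(G, 2, p, "-")
  if (standardize) {
    sc <- sqrt(p * (1 - p))
    X <- sweep(X, 2, sc, "/")
  }
  s <- svd(X)
  k <- min(k, length(s$d))
  ev <- s$d^2 / (n - 1)
  total <- sum(ev)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    v <- s$v[, j]
    if (v[which.max(abs(v))] < 0) {
      s$v[, j] <- -v
      s$u[, j] <- -s$u[, j]
    }
  }
  scores <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], nrow = k)
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(k)))
  structure(list(scores = scores, explained_variance = ev[seq_len(k)],
                 explained_fraction = ev[seq_len(k)] / total,
                 loadings = s$v[, seq_len(k), drop = FALSE],
                 n_sites_used = ncol(G), total_variance = total),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " samples, ", x$n_sites_used,
      " sites; explained fraction: ",
      paste(sprintf("%.3f", x$explained_fraction), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write PCA results in eigenvec/eigenval layout
#'
#' @param pca A [run_pca()] result.
#' @param prefix Output path prefix; writes `<prefix>.eigenvec` (sample id +
#'   one column per component) and `<prefix>.eigenval`.
#' @return `prefix`, invisibly.
#' @export
write_pca_tsv <- function(pca, prefix) {
  ev <- data.frame(sample_id = rownames(pca$scores), pca$scores)
  utils::write.table(ev, paste0(prefix, ".eigenvec"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(eigenval = pca$explained_variance),
                     paste0(prefix, ".eigenval"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
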