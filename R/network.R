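#' Pearson correlation matrix over genes
#'
#' @param expr genes-by-samples matrix (at least 3 samples, no missing values,
#'   no zero-variance genes).
#' @return symmetric genes-by-genes matrix of Pearson r with unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  if (ncol(expr) < 3L) stop("at least 3 samples are required")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  s <- apply(expr, 1L, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[s == 0], 5L), collapse = ", "))
  r <- stats::cor(t(expr))
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

#' Soft-threshold adjacency a_ij = |r_ij|^power (unsigned network)
#'
#' The diagonal is set to zero so row sums are node connectivities.
#' @param corr correlation matrix.
#' @param power soft-threshold exponent (integer >= 1); the package default of
#'   6 is the value used throughout the downstream pipeline.
#' @return adjacency matrix in [0,1] with zero diagonal and attribute `power`.
#' @export
adjacency_matrix <- function(corr, power = 6L) {
  if (power < 1) stop("power must be >= 1")
  a <- abs(corr)^power
  diag(a) <- 0
  attr(a, "power") <- as.integer(power)
  a
}

#' Topological overlap matrix (unsigned TOM)
#'
#' \deqn{TOM_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{\ell_{ij} = \sum_u a_{iu} a_{uj}} and connectivity
#' \eqn{k_i = \sum_u a_{iu}}; \eqn{TOM_{ii} = 1} by convention. The
#' dissimilarity used for clustering is `1 - TOM`.
#'
#' @param adj symmetric adjacency matrix in [0,1] with zero diagonal.
#' @return symmetric TOM matrix in [0,1] with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  if (nrow(adj) != ncol(adj) || max(abs(adj - t(adj))) > 1e-10)
    stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency diagonal must be zero")
  k <- colSums(adj)
  l <- adj %*% adj
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Scale-free topology fit across candidate soft-threshold powers
#'
#' For each candidate power the node connectivities \eqn{k_i} of the resulting
#' adjacency are binned on a log10 scale (10 bins), and log10(frequency) is
#' regressed on log10(mean connectivity per bin). The signed fit index is
#' \eqn{R^2_{signed} = -sign(slope) R^2}: positive when the degree
#' distribution decays (scale-free-like). The chosen power is the smallest
#' candidate reaching `rsq_cutoff`, falling back to the candidate with maximal
#' signed fit.
#'
#' @param corr correlation matrix.
#' @param candidates integer candidate powers.
#' @param rsq_cutoff signed-R2 acceptance threshold (default 0.80).
#' @param n_bins number of connectivity bins (default 10).
#' @return object of class `power_selection`: `table` (power, rsq_signed,
#'   slope, mean_k, median_k, max_k), `power` (chosen), `rsq_cutoff`.
#' @export
pick_soft_threshold <- function(corr, candidates = 1:12, rsq_cutoff = 0.8,
                                n_bins = 10L) {
  if (!length(candidates)) stop("candidates must be non-empty")
  candidates <- sort(unique(as.integer(candidates)))
  rows <- lapply(candidates, function(p) {
    a <- adjacency_matrix(corr, p)
    k <- colSums(a)
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = p, rsq_signed = fit$rsq_signed, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  pass <- which(tab$rsq_signed >= rsq_cutoff)
  chosen <- if (length(pass)) tab$power[pass[1L]]
            else tab$power[which.max(tab$rsq_signed)]
  structure(list(table = tab, power = chosen, rsq_cutoff = rsq_cutoff),
            class = "power_selection")
}

# log-log regression of connectivity histogram; returns signed R^2 and slope.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 2L)
    stop("degenerate connectivity distribution: all connectivities identical")
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1L)
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  bin <- cut(lk, breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  keep <- freq > 0
  if (sum(keep) < 2L)
    stop("degenerate connectivity distribution: binning collapsed")
  x <- log10(vapply(split(k, bin), function(v) if (length(v)) mean(v) else NA_real_,
                    0)[keep])
  y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[["x"]]
  r2 <- summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0
  list(rsq_signed = -sign(slope) * r2, slope = slope)
}

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' @param diss symmetric square matrix with zero diagonal and values in [0,1]
#'   (typically `1 - TOM`).
#' @return an `hclust` tree over genes.
#' @export
hierarchical_cluster <- function(diss) {
  if (nrow(diss) != ncol(diss)) stop("dissimilarity must be square")
  if (max(abs(diss - t(diss))) > 1e-10) stop("dissimilarity must be symmetric")
  if (any(diag(diss) != 0)) stop("dissimilarity diagonal must be zero")
  if (min(diss) < 0 || max(diss) > 1 + 1e-12)
    stop("dissimilarity values must lie in [0, 1]")
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Module color labels in decreasing-size order (largest module = turquoise)
#' @param n number of labels required.
#' @return character vector of n color labels ("gray" is reserved for
#'   unassigned genes and never appears).
#' @export
module_color_sequence <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen",
            "darkturquoise", "darkgrey", "orange", "darkorange", "white",
            "skyblue", "saddlebrown", "steelblue")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("module", seq_len(n - length(base))))
}

#' Dynamic tree cut: adaptive module detection on a dendrogram
#'
#' Hybrid variant: (1) a static cut of the tree at `height_cutoff`; (2) each
#' resulting branch is recursively split at internal merges whose height gap
#' relative to the branch top exceeds a sensitivity threshold controlled by
#' `deep_split` (0 = most conservative, 4 = most aggressive), provided both
#' halves keep at least `min_size` members; (3) clusters smaller than
#' `min_size` are dissolved to the unassigned label `"gray"`; (4) unassigned
#' genes are re-attached to their closest module only when their average
#' dissimilarity to that module is within the range typical of the module's
#' own members. Labels are colors assigned in decreasing module-size order
#' (ties broken by smallest member gene id), largest module = `"turquoise"`.
#'
#' @param dend `hclust` tree from [hierarchical_cluster()].
#' @param diss the dissimilarity matrix the tree was built from.
#' @param height_cutoff static cut height in (0, 1] (default 0.99).
#' @param deep_split integer 0-4 controlling split sensitivity (default 2).
#' @param min_size minimum module size (default 30).
#' @param assign_outliers logical; run stage (4) (default TRUE).
#' @return object of class `module_assignment`: `labels` (named character
#'   vector gene -> color, `"gray"` = unassigned), `sizes`, `params`.
#' @export
dynamic_tree_cut <- function(dend, diss, height_cutoff = 0.99,
                             deep_split = 2L, min_size = 30L,
                             assign_outliers = TRUE) {
  if (min_size < 2L) stop("min_size must be at least 2")
  if (height_cutoff <= 0 || height_cutoff > 1)
    stop("height_cutoff must lie in (0, 1]")
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  genes <- dend$labels
  n <- length(dend$order)
  gap_frac <- c(0.40, 0.30, 0.20, 0.10, 0.05)[deep_split + 1L]

  # leaves and height per internal node
  node_members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    ch <- dend$merge[i, ]
    node_members[[i]] <- c(
      if (ch[1L] < 0) -ch[1L] else node_members[[ch[1L]]],
      if (ch[2L] < 0) -ch[2L] else node_members[[ch[2L]]])
  }
  node_height <- function(node) if (node < 0) 0 else dend$height[node]
  node_size <- function(node) if (node < 0) 1L else length(node_members[[node]])

  split_node <- function(node) {
    if (node < 0 || node_size(node) < 2L * min_size) return(list(node))
    ch <- dend$merge[node, ]
    h_top <- dend$height[node]
    gap <- h_top - max(node_height(ch[1L]), node_height(ch[2L]))
    if (min(node_size(ch[1L]), node_size(ch[2L])) >= min_size &&
        h_top > 0 && gap >= gap_frac * h_top) {
      c(split_node(ch[1L]), split_node(ch[2L]))
    } else list(node)
  }

  # static clusters = maximal subtrees entirely below the cutoff
  static_roots <- list()
  assigned <- rep(FALSE, n)
  # walk merges from the top; a node is a static root if its height <= cutoff
  # and its parent's height > cutoff (or it is the top merge)
  parent <- integer(n - 1L)
  for (i in seq_len(n - 1L)) for (ch in dend$merge[i, ]) if (ch > 0) parent[ch] <- i
  for (i in seq_len(n - 1L)) {
    below <- dend$height[i] <= height_cutoff
    parent_above <- parent[i] == 0L || dend$height[parent[i]] > height_cutoff
    if (below && parent_above) static_roots <- c(static_roots, i)
  }
  # singleton leaves merged only above the cutoff stay unassigned

  clusters <- list()
  for (root in static_roots)
    for (node in split_node(root))
      clusters <- c(clusters, list(
        if (node < 0) -node else node_members[[node]]))

  labels_int <- integer(n)
  for (ci in seq_along(clusters))
    if (length(clusters[[ci]]) >= min_size) labels_int[clusters[[ci]]] <- ci

  # stage 4: conservative dissimilarity-based re-attachment
  if (assign_outliers && any(labels_int > 0) && any(labels_int == 0)) {
    mods <- sort(unique(labels_int[labels_int > 0]))
    thr <- numeric(length(mods))
    centers <- matrix(NA_real_, nrow = n, ncol = length(mods))
    for (j in seq_along(mods)) {
      mem <- which(labels_int == mods[j])
      d_in <- vapply(mem, function(i) mean(diss[i, setdiff(mem, i)]), 0)
      thr[j] <- stats::quantile(d_in, 0.95, names = FALSE)
      centers[, j] <- rowMeans(diss[, mem, drop = FALSE])
    }
    for (i in which(labels_int == 0)) {
      j <- which.min(centers[i, ])
      if (centers[i, j] <= thr[j]) labels_int[i] <- mods[j]
    }
  }

  # relabel by decreasing size, tie-break by smallest member index
  mods <- sort(unique(labels_int[labels_int > 0]))
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(labels_int == m), 0L)
    firsts <- vapply(mods, function(m) min(which(labels_int == m)), 0L)
    ord <- order(-sizes, firsts)
    colors <- module_color_sequence(length(mods))
    lab <- rep("gray", n)
    for (j in seq_along(ord)) lab[labels_int == mods[ord[j]]] <- colors[j]
  } else lab <- rep("gray", n)
  names(lab) <- genes

  sizes <- table(factor(lab[lab != "gray"],
                        levels = module_color_sequence(length(mods))))
  structure(
    list(labels = lab,
         sizes = as.integer(sizes[sizes > 0]) |>
           stats::setNames(names(sizes[sizes > 0])),
         params = list(height_cutoff = height_cutoff,
                       deep_split = as.integer(deep_split),
                       min_size = as.integer(min_size),
                       assign_outliers = assign_outliers)),
    class = "module_assignment")
}

#' Module labels (non-gray) of an assignment, in color/size order
#' @param assignment a `module_assignment`.
#' @return character vector of module colors.
#' @export
module_labels <- function(assignment) names(assignment$sizes)

#' Module eigengenes: first principal component per module
#'
#' Per module the member genes are standardized and the first right singular
#' vector across samples is extracted, rescaled to mean 0 / unit variance and
#' oriented so that it correlates non-negatively with the module's mean
#' standardized expression profile. Unassigned ("gray") genes are excluded.
#'
#' @param expr genes-by-samples matrix containing the module genes.
#' @param assignment a `module_assignment` (or named character vector
#'   gene -> label).
#' @return object of class `module_eigengenes`: `eigengenes`
#'   (samples-by-modules matrix), `variance_explained` (named numeric),
#'   `sample_ids`.
#' @export
module_eigengenes <- function(expr, assignment) {
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels
            else assignment
  mods <- if (inherits(assignment, "module_assignment")) module_labels(assignment)
          else setdiff(unique(labels), "gray")
  me <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
               dimnames = list(colnames(expr), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- intersect(names(labels)[labels == m], rownames(expr))
    if (length(genes) < 2L)
      stop("module ", m, " has fewer than 2 genes in the expression matrix")
    x <- expr[genes, , drop = FALSE]
    if (any(apply(x, 1L, stats::sd) == 0))
      stop("module ", m, " contains constant genes")
    xs <- standardize_rows(x)
    sv <- svd(xs)
    pc <- sv$v[, 1L]
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
    avg <- colMeans(xs)
    orient <- if (stats::sd(avg) > 0) stats::cor(pc, avg) else sum(sv$u[, 1L])
    if (orient < 0) pc <- -pc
    me[, m] <- (pc - mean(pc)) / stats::sd(pc)
  }
  structure(list(eigengenes = me, variance_explained = ve,
                 sample_ids = colnames(expr)),
            class = "module_eigengenes")
}

#' Gene module membership (kME): gene-eigengene correlations
#'
#' @param expr genes-by-samples matrix.
#' @param mes a `module_eigengenes` object computed on the same samples.
#' @return genes-by-modules matrix of Pearson correlations in [-1, 1].
#' @export
gene_module_membership <- function(expr, mes) {
  if (!identical(colnames(expr), mes$sample_ids))
    stop("expression samples do not match eigengene samples")
  s <- apply(expr, 1L, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[s == 0], 5L), collapse = ", "))
  kme <- stats::cor(t(expr), mes$eigengenes)
  kme[kme > 1] <- 1; kme[kme < -1] <- -1
  kme
}

#' Export a weighted edge list from an adjacency or TOM matrix
#' @param mat symmetric genes-by-genes matrix.
#' @param threshold minimum weight to keep an edge.
#' @return data.frame gene1/gene2/weight (upper triangle only).
#' @export
edge_list <- function(mat, threshold = 0) {
  idx <- which(upper.tri(mat) & mat > threshold, arr.ind = TRUE)
  data.frame(gene1 = rownames(mat)[idx[, 1L]],
             gene2 = colnames(mat)[idx[, 2L]],
             weight = mat[idx], stringsAsFactors = FALSE)
}
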