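## Fluorescence spot quantification: prominence-based local-maxima
## detection (the "noise tolerance" style of maxima finding), control-driven
## threshold selection, and nonparametric group comparison.

#' Peak persistence of a 2-D intensity grid
#'
#' Computes every candidate maximum of the image together with its
#' prominence: pixels are processed in decreasing intensity order with a
#' union-find over 8-connected components. When a component merges into one
#' with a higher (or equal-valued, smaller-index) peak at level v, it dies
#' with prominence \code{peak - v}; the surviving global maximum is always
#' reported, with prominence \code{Inf} (a constant image has no maxima at
#' all). Connected equal-valued plateaus
#' count as a single maximum represented by the member pixel closest to the
#' plateau centroid. Thresholding these prominences at any tolerance t
#' yields exactly the maxima whose basin, flooded down from the peak to
#' \code{peak - t}, contains no higher pixel (equal peaks collapse to one).
#'
#' @param image numeric matrix, finite values.
#' @return data.frame with \code{row}, \code{col}, \code{value},
#'   \code{prominence}, one row per candidate maximum.
#' @export
peak_persistence <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  nr <- nrow(image); nc <- ncol(image)
  n <- nr * nc
  v <- as.vector(image)
  ord <- order(-v, seq_len(n))

  parent <- integer(n)                 # 0 = not yet added
  peak_val <- numeric(n)
  min_idx <- integer(n)                # smallest peak-cell index in comp
  cells <- vector("list", n)           # peak plateau cells per root

  find <- function(x) {
    r <- x
    while (parent[r] != r) r <- parent[r]
    while (parent[x] != r) { nx <- parent[x]; parent[x] <<- r; x <- nx }
    r
  }

  deaths_row <- integer(0); deaths_col <- integer(0)
  deaths_val <- numeric(0); deaths_prom <- numeric(0)

  record <- function(root, prom) {
    cc <- cells[[root]]
    rows <- (cc - 1L) %% nr + 1L
    cols <- (cc - 1L) %/% nr + 1L
    cr <- mean(rows); cg <- mean(cols)
    d2 <- (rows - cr)^2 + (cols - cg)^2
    pick <- cc[order(d2, cc)][1]
    deaths_row <<- c(deaths_row, (pick - 1L) %% nr + 1L)
    deaths_col <<- c(deaths_col, (pick - 1L) %/% nr + 1L)
    deaths_val <<- c(deaths_val, peak_val[root])
    deaths_prom <<- c(deaths_prom, prom)
  }

  for (p in ord) {
    vp <- v[p]
    parent[p] <- p
    peak_val[p] <- vp
    min_idx[p] <- p
    cells[[p]] <- p
    pr <- (p - 1L) %% nr + 1L
    pc <- (p - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      qr <- pr + dr; qc <- pc + dc
      if (qr < 1L || qr > nr || qc < 1L || qc > nc) next
      q <- qr + (qc - 1L) * nr
      if (parent[q] == 0L) next
      r1 <- find(p); r2 <- find(q)
      if (r1 == r2) next
      ## survivor: higher peak; tie broken by smaller peak-cell index
      if (peak_val[r1] > peak_val[r2] ||
          (peak_val[r1] == peak_val[r2] && min_idx[r1] < min_idx[r2])) {
        surv <- r1; dying <- r2
      } else {
        surv <- r2; dying <- r1
      }
      prom <- peak_val[dying] - vp
      if (peak_val[dying] == vp && peak_val[surv] == vp) {
        ## plateau at peak level: same maximum, pool its cells
        cells[[surv]] <- c(cells[[surv]], cells[[dying]])
        min_idx[surv] <- min(min_idx[surv], min_idx[dying])
      } else if (prom > 0) {
        record(dying, prom)
      }
      parent[dying] <- surv
      cells[dying] <- list(NULL)
    }
  }
  root <- find(ord[1])
  if (peak_val[root] > min(v)) record(root, Inf)

  out <- data.frame(row = deaths_row, col = deaths_col,
                    value = deaths_val, prominence = deaths_prom)
  out[order(-out$value, out$row, out$col), , drop = FALSE]
}

#' Find local maxima above a prominence threshold
#'
#' Reports the maxima of [peak_persistence()] with prominence strictly
#' greater than \code{prominence}, sorted by descending intensity.
#'
#' @param image numeric matrix.
#' @param prominence non-negative tolerance t.
#' @return object of class \code{spot_callset}: list with
#'   \code{threshold}, \code{maxima} (data.frame: x = column, y = row,
#'   intensity, prominence) and \code{count}.
#' @export
find_maxima <- function(image, prominence) {
  stopifnot(prominence >= 0)
  pp <- peak_persistence(image)
  sel <- pp[pp$prominence > prominence, , drop = FALSE]
  maxima <- data.frame(x = sel$col, y = sel$row, intensity = sel$value,
                       prominence = sel$prominence)
  rownames(maxima) <- NULL
  structure(list(threshold = prominence, maxima = maxima,
                 count = nrow(maxima)), class = "spot_callset")
}

#' @export
print.spot_callset <- function(x, ...) {
  cat(sprintf("Spot call set: %d maxima at prominence > %g\n",
              x$count, x$threshold))
  invisible(x)
}

#' Choose a prominence threshold from control images
#'
#' Scans a grid of candidate thresholds and returns the one maximizing
#' mean spot count on positive controls minus mean count on negative
#' controls, subject to the negative-control mean not exceeding
#' \code{neg_cap} (default 1 spot per image). Ties prefer the larger
#' threshold; if no grid value satisfies the cap, the largest grid value is
#' returned with a warning.
#'
#' @param pos_images,neg_images lists of numeric matrices (>= 1 each).
#' @param grid numeric vector of candidate thresholds (non-empty).
#' @param neg_cap maximum tolerated mean negative-control count.
#' @return the chosen threshold, with the per-threshold summary attached as
#'   attribute \code{"grid_summary"}.
#' @export
optimize_threshold <- function(pos_images, neg_images, grid, neg_cap = 1) {
  if (length(grid) == 0L) stop("empty threshold grid")
  if (length(pos_images) == 0L || length(neg_images) == 0L)
    stop("need at least one image per control class")
  proms_pos <- lapply(pos_images, function(im) peak_persistence(im)$prominence)
  proms_neg <- lapply(neg_images, function(im) peak_persistence(im)$prominence)
  count_at <- function(proms, t)
    mean(vapply(proms, function(p) sum(p > t), numeric(1)))
  summ <- data.frame(
    threshold = grid,
    mean_pos = vapply(grid, count_at, numeric(1), proms = proms_pos),
    mean_neg = vapply(grid, count_at, numeric(1), proms = proms_neg))
  summ$objective <- summ$mean_pos - summ$mean_neg
  feasible <- summ$mean_neg <= neg_cap
  if (!any(feasible)) {
    warning("no threshold meets the negative-control cap; ",
            "returning the largest grid value")
    chosen <- max(grid)
  } else {
    f <- summ[feasible, ]
    chosen <- max(f$threshold[f$objective == max(f$objective)])
  }
  attr(chosen, "grid_summary") <- summ
  chosen
}

#' Compare per-image spot counts between groups
#'
#' Kruskal-Wallis omnibus test (tie-corrected, via \code{kruskal.test})
#' followed by Dunn's pairwise z tests on the pooled ranks with
#' Benjamini-Hochberg adjustment across all pairs.
#'
#' @param counts named list: one numeric vector of per-image counts per
#'   group (>= 2 groups, each n >= 2).
#' @return object of class \code{group_comparison}: list with
#'   \code{omnibus} (statistic, df, p_value) and \code{pairwise}
#'   (data.frame: group1, group2, z, p_raw, p_adj, significant at 0.05).
#' @export
compare_groups <- function(counts) {
  if (length(counts) < 2L) stop("need at least two groups")
  if (any(lengths(counts) < 2L)) stop("each group needs n >= 2")
  g <- factor(rep(names(counts), lengths(counts)), levels = names(counts))
  x <- unlist(counts, use.names = FALSE)
  kw <- kruskal.test(x, g)

  r <- rank(x)
  N <- length(x)
  mean_rank <- tapply(r, g, mean)
  n_g <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term

  combs <- utils::combn(levels(g), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    ia <- match(a, levels(g)); ib <- match(b, levels(g))
    se <- sqrt(base_var * (1 / n_g[ia] + 1 / n_g[ib]))
    z <- as.numeric(mean_rank[a] - mean_rank[b]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p_raw = 2 * pnorm(-abs(z)))
  }))
  pw$p_adj <- p.adjust(pw$p_raw, method = "BH")
  pw$significant <- pw$p_adj < 0.05
  structure(list(
    omnibus = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter),
                   p_value = kw$p.value),
    pairwise = pw), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4f, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Read a grayscale spot image from TIFF or PNG
#'
#' Multi-channel images are averaged to one channel.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @return numeric matrix.
#' @export
read_spot_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}
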