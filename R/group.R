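#' All-pairs similarity matrix for a set of organisms
#'
#' Runs [compare_pair()] once per unordered pair of networks and assembles
#' the symmetric organisms-by-organisms table of one global index. The
#' diagonal is 1 by definition (an organism compared with itself) and is not
#' computed.
#'
#' @param nets list of \code{two_level_network}s, all built over the same
#'   universe and ubiquitous list, with distinct organism codes.
#' @param index one of \code{"psim"}, \code{"psim_w"}, \code{"ssim"},
#'   \code{"csim"}.
#' @param mode reaction-collection mode, \code{"set"} or \code{"multiset"}.
#' @return An object of class \code{similarity_matrix}: a list with
#'   \code{organisms}, \code{index}, \code{mode} and \code{values} (square
#'   numeric matrix with organism-code dimnames).
#' @export
similarity_matrix <- function(nets, index = c("psim", "psim_w", "ssim", "csim"),
                              mode = c("set", "multiset")) {
  index <- match.arg(index)
  mode <- match.arg(mode)
  if (length(nets) < 2L) {
    stop("at least two organisms are needed", call. = FALSE)
  }
  for (net in nets) check_comparable(nets[[1]], net)
  orgs <- unname(vapply(nets, `[[`, character(1), "org"))
  if (anyDuplicated(orgs)) {
    stop("duplicate organism codes: ", paste(orgs[duplicated(orgs)], collapse = ", "),
      call. = FALSE
    )
  }
  n <- length(orgs)
  values <- matrix(1, n, n, dimnames = list(orgs, orgs))
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      cmp <- compare_pair(nets[[a]], nets[[b]], mode)
      values[a, b] <- values[b, a] <- cmp[[index]]
    }
  }
  structure(
    list(organisms = unname(orgs), index = index, mode = mode, values = values),
    class = "similarity_matrix"
  )
}

#' Wrap a plain numeric matrix as a similarity matrix
#'
#' Validates and wraps an externally produced (or read-back) square table of
#' pairwise similarities so it can be clustered or rendered.
#'
#' @param values square numeric matrix with organism codes as dimnames;
#'   symmetric, unit diagonal, entries in \eqn{[0, 1]} or \code{NA}.
#' @param index name of the index the values came from.
#' @param mode reaction-collection mode label.
#' @return a \code{similarity_matrix}.
#' @export
as_similarity_matrix <- function(values, index = "psim", mode = "set") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  orgs <- rownames(values)
  if (is.null(orgs) || !identical(orgs, colnames(values))) {
    stop("the matrix needs matching organism-code row and column names",
      call. = FALSE
    )
  }
  if (any(abs(values - t(values)) > 1e-12, na.rm = TRUE)) {
    stop("the similarity matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(values) - 1) > 1e-12, na.rm = TRUE)) {
    stop("the similarity matrix diagonal must be 1", call. = FALSE)
  }
  finite <- values[!is.na(values)]
  if (any(finite < 0 | finite > 1)) {
    stop("similarity values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(organisms = orgs, index = index, mode = mode, values = values),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, digits = 4, ...) {
  cat(sprintf(
    "%d x %d similarity matrix (index %s, %s mode)\n",
    nrow(x$values), ncol(x$values), x$index, x$mode
  ))
  print(round(x$values, digits))
  invisible(x)
}

#' Write / read a similarity matrix as TSV
#'
#' TSV with a header row and column of organism codes; values at full
#' precision so a read-back matrix clusters identically.
#'
#' @param sm a \code{similarity_matrix}.
#' @param file path of the TSV file.
#' @return \code{write_similarity_matrix}: the path, invisibly.
#' @export
write_similarity_matrix <- function(sm, file) {
  stopifnot(inherits(sm, "similarity_matrix"))
  header <- paste(c("organism", colnames(sm$values)), collapse = "\t")
  body <- vapply(
    rownames(sm$values),
    function(o) paste(c(o, num_fmt(sm$values[o, ])), collapse = "\t"),
    character(1)
  )
  writeLines(c(header, body), file)
  invisible(file)
}

#' @rdname write_similarity_matrix
#' @param index,mode labels attached to the read-back matrix.
#' @return \code{read_similarity_matrix}: a \code{similarity_matrix}.
#' @export
read_similarity_matrix <- function(file, index = "psim", mode = "set") {
  tab <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  orgs <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- orgs
  storage.mode(values) <- "double"
  as_similarity_matrix(values, index = index, mode = mode)
}

## full-precision numeric formatting shared by the TSV/CSV writers;
## round-trips doubles exactly (17 significant digits), integers compactly
num_fmt <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == round(v) && abs(v) < 1e15) {
      sprintf("%d", as.integer(v))
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
  out
}

#' Complete-linkage hierarchical clustering of organisms
#'
#' Agglomerates organisms on the distance \eqn{d = 1 - s}, where \eqn{s} is
#' the pairwise global similarity index, using complete linkage (the
#' distance between two clusters is the maximum pairwise distance between
#' their members). Ties in the minimal linkage distance are broken
#' deterministically: each cluster is labelled by the lexicographically
#' smallest organism code among its members, and the candidate pair whose
#' sorted label pair is lexicographically smallest is merged first, so a
#' given matrix always yields the same dendrogram.
#'
#' @param sm a complete \code{similarity_matrix} (no missing values; a
#'   matrix with an undefined weighted index is refused, never imputed).
#' @return an object of class \code{hclust} (merge heights on the
#'   \eqn{1 - s} distance scale, in \eqn{[0, 1]}), usable with
#'   [stats::cutree()], [plot()] and [ape::as.phylo()].
#' @export
cluster_organisms <- function(sm) {
  stopifnot(inherits(sm, "similarity_matrix"))
  values <- sm$values
  if (anyNA(values)) {
    idx <- which(is.na(values) & upper.tri(values), arr.ind = TRUE)
    pairs <- apply(idx, 1L, function(ij) {
      paste(rownames(values)[ij[1]], colnames(values)[ij[2]], sep = "-")
    })
    stop(
      "missing similarity values (undefined index) for pairs: ",
      paste(pairs, collapse = ", "), "; clustering refuses to impute",
      call. = FALSE
    )
  }
  n <- nrow(values)
  if (n < 2L) stop("at least two organisms are needed", call. = FALSE)
  labels <- rownames(values)
  d <- 1 - values
  diag(d) <- Inf

  ## active clusters: id (negative singleton / positive merge row), label
  ## (lexicographically smallest member code), current linkage distances
  ids <- -seq_len(n)
  labs <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(ids)
    best <- NULL
    best_d <- Inf
    best_lab <- NULL
    for (a in seq_len(m - 1L)) {
      for (b in seq.int(a + 1L, m)) {
        lab <- sort(c(labs[a], labs[b]))
        better <- d[a, b] < best_d - 1e-15 ||
          (abs(d[a, b] - best_d) <= 1e-15 && (
            is.null(best_lab) ||
              lab[1] < best_lab[1] ||
              (lab[1] == best_lab[1] && lab[2] < best_lab[2])
          ))
        if (better) {
          best <- c(a, b)
          best_d <- d[a, b]
          best_lab <- lab
        }
      }
    }
    a <- best[1]
    b <- best[2]
    pair <- sort(c(ids[a], ids[b]))
    merge[step, ] <- pair
    height[step] <- best_d

    ## complete linkage: new cluster's distance is the max of the two
    keep <- setdiff(seq_len(m), c(a, b))
    new_d <- pmax(d[a, keep], d[b, keep])
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, new_d), c(new_d, Inf))
    ids <- c(ids[keep], step)
    labs <- c(labs[keep], min(labs[c(a, b)]))
  }

  order <- hclust_leaf_order(merge)
  structure(
    list(
      merge = merge, height = height, order = order, labels = labels,
      method = "complete", call = match.call(),
      dist.method = paste0("1 - ", sm$index)
    ),
    class = "hclust"
  )
}

## left-to-right leaf order by recursive traversal of the merge tree
hclust_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Write a dendrogram as Newick
#'
#' Converts an \code{hclust} tree (such as the result of
#' [cluster_organisms()]) to a phylogeny with branch lengths derived from
#' the merge heights and writes it in Newick format.
#'
#' @param hc an \code{hclust} object.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_newick <- function(hc, file) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = file)
  invisible(file)
}

#' Render a similarity matrix as a colour map
#'
#' Heatmap of a similarity matrix with rows and columns in organism order,
#' row 1 at the top. The colour scale runs from yellow (similarity 1 — the
#' main diagonal is always yellow) to blue (similarity 0). Output is
#' deterministic for fixed input and device size.
#'
#' @param sm a complete \code{similarity_matrix}.
#' @param file output path ending in \code{.png} or \code{.svg}.
#' @param width,height device size in pixels (PNG) or inches (SVG).
#' @return the path, invisibly.
#' @export
render_matrix <- function(sm, file, width = 480, height = 480) {
  stopifnot(inherits(sm, "similarity_matrix"))
  if (anyNA(sm$values)) {
    stop("cannot render a similarity matrix with missing values", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    grDevices::png(file, width = width, height = height)
  } else if (ext == "svg") {
    if (!capabilities("cairo")) {
      stop("SVG output needs cairo support; use a .png path", call. = FALSE)
    }
    grDevices::svg(file, width = width, height = height)
  } else {
    stop("unsupported image format '", ext, "' (use png or svg)", call. = FALSE)
  }
  on.exit(grDevices::dev.off(), add = TRUE)

  n <- nrow(sm$values)
  pal <- grDevices::colorRampPalette(c("#0000CC", "#FFFF00"))(256)
  ## image() draws y bottom-up; flip rows so organism 1 sits on top
  z <- t(sm$values[n:1, , drop = FALSE])
  graphics::par(mar = c(1.5, 4.5, 4.5, 1.5))
  graphics::image(
    x = seq_len(n), y = seq_len(n), z = z, zlim = c(0, 1), col = pal,
    axes = FALSE, xlab = "", ylab = "",
    main = sprintf("similarity (%s)", sm$index)
  )
  graphics::axis(3, at = seq_len(n), labels = sm$organisms, las = 2, tick = FALSE)
  graphics::axis(2, at = seq_len(n), labels = rev(sm$organisms), las = 2, tick = FALSE)
  graphics::box()
  invisible(file)
}
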