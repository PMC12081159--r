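# Immune-inspired memory-cell nearest-prototype classifier.
#
# Prototype ("memory cell") maintenance follows the AIRS family: candidates
# far from every same-label cell (farther than the average pairwise affinity
# of the training set) found a new cell; candidates close to an existing cell
# stimulate it and pull it toward themselves by a running mean (area growth);
# at capacity the least-stimulated cell is evicted.

#' Average pairwise affinity of a feature set
#'
#' Affinity is the Euclidean distance divided by sqrt(p), so features in
#' \[0, 1\] yield affinities in \[0, 1\]. The threshold is the mean affinity
#' over all n(n-1)/2 unordered pairs.
#'
#' @param x numeric matrix (rows = feature vectors), n >= 2.
#' @return mean pairwise affinity.
#' @export
similarity_threshold <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two feature vectors")
  mean(stats::dist(x)) / sqrt(ncol(x))
}

#' Train a memory-cell classifier
#'
#' Training examples are presented in a seeded random order. Features are
#' min-max normalized column-wise using the training data (constant columns
#' map to 0), and all distances are divided by sqrt(p) so they lie in
#' \[0, 1\]. A candidate whose affinity to the nearest same-label cell
#' exceeds the similarity threshold becomes a new cell; otherwise it
#' increments that cell's stimulation count and moves the cell toward itself
#' by step 1/stimulation (a running mean over its stimulating candidates).
#' When adding a cell would exceed `capacity`, the least-stimulated cell is
#' evicted (ties: lowest index), never removing the last cell of a class.
#'
#' @param x numeric matrix of training features (rows = examples).
#' @param y class labels, exactly two classes, each with >= 1 example.
#' @param capacity maximum number of cells (default 64).
#' @param seed presentation-order seed.
#' @param positive label treated as the positive (malignant-like) class for
#'   scoring; defaults to `"malignant"` when present, else the second sorted
#'   level.
#' @return object of class `"memcell"`.
#' @seealso [predict.memcell()], [similarity_threshold()]
#' @export
memcell <- function(x, y, capacity = 64L, seed = 1L, positive = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ")
  lv <- sort(unique(y))
  if (length(lv) != 2) stop("exactly two classes required")
  if (is.null(positive)) {
    positive <- if ("malignant" %in% lv) "malignant" else lv[2]
  }
  if (!positive %in% lv) stop("positive label not present in y")
  p <- ncol(x)
  rmin <- apply(x, 2, min)
  span <- apply(x, 2, max) - rmin
  span[span == 0] <- 1
  xn <- sweep(sweep(x, 2, rmin, "-"), 2, span, "/")
  thr <- similarity_threshold(xn)
  ord <- with_seed(seed, sample.int(nrow(xn)))
  sq <- sqrt(p)
  cells <- matrix(0, 0, p)
  clab <- character(0)
  stim <- integer(0)

  add_cell <- function(v, li) {
    if (nrow(cells) >= capacity) {
      byst <- order(stim, seq_along(stim))
      for (k in byst) {
        # eviction must leave >= 1 cell of every class (counting the newcomer)
        left <- sum(clab == clab[k]) - 1L + (li == clab[k])
        if (left >= 1L) {
          cells <<- cells[-k, , drop = FALSE]
          clab <<- clab[-k]
          stim <<- stim[-k]
          break
        }
      }
    }
    cells <<- rbind(cells, v)
    clab <<- c(clab, li)
    stim <<- c(stim, 1L)
  }

  for (ii in ord) {
    v <- xn[ii, ]
    li <- y[ii]
    same <- which(clab == li)
    if (!length(same)) {
      add_cell(v, li)
      next
    }
    dd <- sqrt(colSums((t(cells[same, , drop = FALSE]) - v)^2)) / sq
    jrel <- which.min(dd)                      # ties: lowest index
    if (dd[jrel] > thr) {
      add_cell(v, li)
    } else {
      j <- same[jrel]
      stim[j] <- stim[j] + 1L
      cells[j, ] <- cells[j, ] + (v - cells[j, ]) / stim[j]
    }
  }
  dimnames(cells) <- NULL
  structure(list(cells = cells, cell_labels = clab, stimulation = stim,
                 threshold = thr, levels = lv, positive = positive,
                 center = rmin, scale = span, capacity = as.integer(capacity),
                 seed = as.integer(seed), n_train = nrow(x),
                 call = match.call()),
            class = "memcell")
}

#' Classify with a memory-cell model
#'
#' Labels come from the nearest cell. The score is
#' `d_other / (d_same + d_other)` where `d_same` / `d_other` are the
#' distances to the nearest cell of the positive / negative class, so it
#' lies in \[0, 1\] and is higher for more malignant-like queries (0.5 when
#' equidistant).
#'
#' @param object a [memcell()] model.
#' @param newdata numeric matrix of feature rows on the training scale
#'   (normalization is applied internally).
#' @param type `"class"`, `"score"`, or `"both"`.
#' @param ... ignored.
#' @return character vector, numeric vector, or a data frame with both.
#' @export
predict.memcell <- function(object, newdata, type = c("class", "score", "both"),
                            ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != ncol(object$cells)) stop("feature dimension mismatch")
  xn <- sweep(sweep(x, 2, object$center, "-"), 2, object$scale, "/")
  sq <- sqrt(ncol(x))
  pos <- object$cell_labels == object$positive
  cls <- character(nrow(xn))
  sco <- numeric(nrow(xn))
  tc <- t(object$cells)
  for (i in seq_len(nrow(xn))) {
    d <- sqrt(colSums((tc - xn[i, ])^2)) / sq
    cls[i] <- object$cell_labels[which.min(d)]
    dp <- min(d[pos])
    dn <- min(d[!pos])
    sco[i] <- if (dp + dn == 0) 0.5 else dn / (dp + dn)
  }
  switch(type,
         class = cls,
         score = sco,
         both = data.frame(class = cls, score = sco))
}

#' @export
print.memcell <- function(x, ...) {
  cat("Memory-cell classifier\n")
  cat(sprintf("  classes: %s (positive: %s)\n",
              paste(x$levels, collapse = " / "), x$positive))
  cat(sprintf("  cells: %d (capacity %d), features: %d\n",
              nrow(x$cells), x$capacity, ncol(x$cells)))
  cat(sprintf("  similarity threshold: %.4f, trained on %d examples\n",
              x$threshold, x$n_train))
  invisible(x)
}

#' @export
summary.memcell <- function(object, ...) {
  tab <- table(object$cell_labels)
  cat("Memory-cell classifier summary\n")
  cat(sprintf("  training examples: %d, similarity threshold: %.4f\n",
              object$n_train, object$threshold))
  cat("  cells per class:\n")
  for (l in names(tab)) {
    st <- object$stimulation[object$cell_labels == l]
    cat(sprintf("    %-10s %3d cells, stimulation %d-%d (median %.0f)\n",
                l, tab[[l]], min(st), max(st), stats::median(st)))
  }
  invisible(object)
}

#' Save a memory-cell model as plain text
#'
#' Writes `cells.csv` (one row per cell: features, label, stimulation) and
#' `model.json` (threshold, normalization statistics, labels, capacity) into
#' `dir`, so trained models survive sessions without binary serialization.
#'
#' @param model a [memcell()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_memcell <- function(model, dir) {
  stopifnot(inherits(model, "memcell"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- as.data.frame(model$cells)
  names(cells) <- paste0("f", seq_len(ncol(model$cells)))
  cells$label <- model$cell_labels
  cells$stimulation <- model$stimulation
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(threshold = model$threshold, levels = model$levels,
         positive = model$positive, center = model$center,
         scale = model$scale, capacity = model$capacity,
         seed = model$seed, n_train = model$n_train),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a memory-cell model saved by [write_memcell()]
#'
#' @param dir directory containing `cells.csv` and `model.json`.
#' @return a `"memcell"` object.
#' @export
read_memcell <- function(dir) {
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  fcol <- grep("^f[0-9]+$", names(cells))
  structure(list(cells = unname(as.matrix(cells[, fcol])),
                 cell_labels = cells$label,
                 stimulation = as.integer(cells$stimulation),
                 threshold = meta$threshold, levels = meta$levels,
                 positive = meta$positive, center = meta$center,
                 scale = meta$scale, capacity = as.integer(meta$capacity),
                 seed = as.integer(meta$seed),
                 n_train = as.integer(meta$n_train), call = NULL),
            class = "memcell")
}
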