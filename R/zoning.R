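# Functional zones from graph modules, and their correspondence with
# anatomical microzones measured by normalised mutual information.

.greek <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
            "theta", "iota", "kappa", "lambda", "mu", "nu", "xi",
            "omicron", "pi", "rho", "sigma", "tau", "upsilon")

.greek_name <- function(i) {
  if (i <= length(.greek)) .greek[i] else paste0("mod", i)
}

#' Label map columns by functional zone
#'
#' Translates a graph module partition of the columns into functional
#' zone labels. Under the `"contiguous"` definition every maximal run of
#' consecutive columns sharing a module becomes its own zone
#' (`alpha1`, `beta1`, `alpha2`, ...), so zones are spatially connected
#' ranges like anatomical microzones; a module split across disjoint
#' ranges yields several zones. Under `"modulewise"` the spatial
#' connectedness requirement is dropped and labels are simply the module
#' names (`alpha`, `beta`, ...).
#'
#' @param partition a `module_partition` from [detect_modules()], or an
#'   integer membership vector, ordered along the mediolateral axis.
#' @param definition `"contiguous"` or `"modulewise"`.
#' @return object of class `zone_labeling`: character vector with
#'   attribute `kind`.
#' @export
functional_zones <- function(partition,
                             definition = c("contiguous", "modulewise")) {
  definition <- match.arg(definition)
  m <- if (inherits(partition, "module_partition")) partition$membership else partition
  m <- .canonical_membership(m)
  if (definition == "modulewise") {
    lab <- vapply(m, .greek_name, character(1))
    return(structure(lab, kind = "functional_modulewise",
                     class = "zone_labeling"))
  }
  runs <- rle(m)
  counter <- integer(max(m))
  lab <- character(0)
  for (i in seq_along(runs$values)) {
    v <- runs$values[i]
    counter[v] <- counter[v] + 1L
    lab <- c(lab, rep(paste0(.greek_name(v), counter[v]), runs$lengths[i]))
  }
  structure(lab, kind = "functional_contiguous", class = "zone_labeling")
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between two zone labelings
#'
#' Plug-in mutual information (natural log) between the empirical label
#' distributions of two equally long labelings, normalised by the larger
#' of the two entropies so that the headline value lies in \[0, 1\], with
#' 1 denoting perfect overlap (identity up to relabeling). Two constant
#' labelings are a perfect overlap and return normalised MI 1.
#'
#' @param x,y `zone_labeling`s or plain vectors of equal length.
#' @return object of class `mi_result`: list with `mi` (nats), `h_x`,
#'   `h_y`, `nmi`.
#' @export
normalized_mi <- function(x, y) {
  x <- as.character(x); y <- as.character(y)
  if (length(x) != length(y)) stop("labelings must have equal length")
  n <- length(x)
  joint <- table(x, y) / n
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
  }
  mi <- as.numeric(mi)
  hx <- .entropy(px); hy <- .entropy(py)
  hmax <- max(hx, hy)
  nmi <- if (hmax == 0) 1 else mi / hmax
  structure(list(mi = mi, h_x = hx, h_y = hy, nmi = nmi),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("MI = %.4f nats (H_x = %.4f, H_y = %.4f), normalised MI = %.4f\n",
              x$mi, x$h_x, x$h_y, x$nmi))
  invisible(x)
}

#' Permutation chance level for the normalised MI
#'
#' Re-evaluates the normalised MI after shuffling the structural labels
#' across columns. The default `"column"` unit permutes labels freely
#' (destroying the spatial contiguity of structural zones); `"block"`
#' permutes the order of the contiguous label blocks instead, preserving
#' zone shapes.
#'
#' @param x structural labeling (shuffled), `zone_labeling` or vector.
#' @param y functional labeling (held fixed).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param unit `"column"` or `"block"`.
#' @return list with `chance` (vector of permuted normalised MIs), `ci`
#'   (2.5 and 97.5 percentiles), `actual` (unpermuted normalised MI).
#' @export
mi_chance <- function(x, y, n_perm = 1000, seed = 1,
                      unit = c("column", "block")) {
  unit <- match.arg(unit)
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  x <- as.character(x); y <- as.character(y)
  set.seed(seed)
  perm_one <- function() {
    if (unit == "column") {
      sample(x)
    } else {
      runs <- rle(x)
      ord <- sample(seq_along(runs$values))
      inverse.rle(list(values = runs$values[ord],
                       lengths = runs$lengths[ord]))
    }
  }
  chance <- vapply(seq_len(n_perm), function(i) normalized_mi(perm_one(), y)$nmi,
                   numeric(1))
  list(
    chance = chance,
    ci = stats::quantile(chance, c(0.025, 0.975), names = FALSE),
    actual = normalized_mi(x, y)$nmi
  )
}
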