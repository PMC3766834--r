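#' Construct a Pedigree from parent/offspring records
#'
#' Records may arrive in any order; a topological order (parents before
#' offspring) is computed on construction. The tokens \code{"0"}, \code{""}
#' and \code{NA} all denote an unknown parent.
#'
#' @param id character vector of individual identifiers (unique)
#' @param sire,dam parent identifiers, \code{NA}/\code{"0"} for unknown
#' @param sex one of \code{"M"}, \code{"F"}, \code{"U"} per individual;
#'   defaults to \code{"U"}
#' @param cohort integer generation/cohort index; defaults to 1 for founders
#'   and 1 + max parental cohort otherwise
#' @return a [Pedigree-class] object in topological order
#' @examples
#' ped <- Pedigree(id = c("c", "p1", "p2"), sire = c("p1", NA, NA),
#'                 dam = c("p2", NA, NA))
#' ids(ped)  # parents reordered before the child
#' @export
Pedigree <- function(id, sire = NA, dam = NA, sex = NULL, cohort = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (n == 0L) stop("empty pedigree")
  clean <- function(p) {
    p <- rep_len(as.character(p), n)
    p[p %in% c("0", "") | is.na(p)] <- NA_character_
    p
  }
  sire <- clean(sire)
  dam <- clean(dam)
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  missing_par <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(missing_par))
    stop("parent id(s) not present as individuals: ",
         paste(missing_par, collapse = ", "))
  ord <- topoOrder(id, sire, dam)
  if (is.null(sex)) sex <- rep("U", n) else sex <- rep_len(as.character(sex), n)
  if (is.null(cohort)) {
    cohort <- rep(NA_integer_, n)
    pos <- match(id, id)
    for (k in ord) {
      pc <- c(if (!is.na(sire[k])) cohort[match(sire[k], id)],
              if (!is.na(dam[k])) cohort[match(dam[k], id)])
      cohort[k] <- if (length(pc)) max(pc) + 1L else 1L
    }
  } else cohort <- as.integer(rep_len(cohort, n))
  new("Pedigree", id = id[ord], sire = sire[ord], dam = dam[ord],
      sex = sex[ord], cohort = cohort[ord])
}

# Kahn topological sort over the parent -> offspring DAG; errors on cycles,
# naming the individuals involved.
topoOrder <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    k <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, k)
    for (ch in children[[k]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  ord
}

#' Sire/dam accessors
#'
#' @param x a Pedigree
#' @return named character vector of parent ids (\code{NA} = unknown)
#' @export
sires <- function(x) stats::setNames(x@sire, x@id)

#' @rdname sires
#' @export
dams <- function(x) stats::setNames(x@dam, x@id)

#' @rdname sires
#' @export
cohorts <- function(x) stats::setNames(x@cohort, x@id)

#' @rdname sires
#' @export
sexes <- function(x) stats::setNames(x@sex, x@id)

#' Founder indicator
#'
#' @param x a Pedigree
#' @return logical vector, TRUE where both parents are unknown
#' @export
isFounder <- function(x) stats::setNames(is.na(x@sire) & is.na(x@dam), x@id)

#' Expected additive relationship matrix (tabular method)
#'
#' Computes the pedigree-expected additive relationship matrix A (twice the
#' kinship coefficients) by the tabular recursion in topological order:
#' \deqn{A_{ii} = 1 + \tfrac12 A_{s(i), d(i)}, \qquad
#'       A_{ij} = \tfrac12 (A_{j, s(i)} + A_{j, d(i)})}
#' with an unknown parent contributing 0 (treated as an unrelated,
#' non-inbred founder). Founders are assumed non-inbred, so the diagonal is
#' \eqn{1 + F_i} with \eqn{F_i} the inbreeding coefficient.
#'
#' @param pedigree a [Pedigree-class]
#' @return a [RelationshipMatrix-class] with \code{kind = "pedigree_A"}
#' @examples
#' ped <- Pedigree(id = c("p1", "p2", "c1", "c2"),
#'                 sire = c(NA, NA, "p1", "p1"), dam = c(NA, NA, "p2", "p2"))
#' relValues(buildA(ped))["c1", "c2"]  # full sibs: 0.5
#' @export
buildA <- function(pedigree) {
  stopifnot(is(pedigree, "Pedigree"))
  n <- length(pedigree@id)
  si <- match(pedigree@sire, pedigree@id)
  di <- match(pedigree@dam, pedigree@id)
  A <- matrix(0, n, n, dimnames = list(pedigree@id, pedigree@id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      idx <- seq_len(i - 1L)
      v <- 0.5 * ((if (is.na(s)) 0 else A[idx, s]) +
                  (if (is.na(d)) 0 else A[idx, d]))
      A[idx, i] <- v
      A[i, idx] <- v
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  new("RelationshipMatrix", values = A, kind = "pedigree_A")
}

#' Pairwise additive relationship by recursive kinship
#'
#' Independent of [buildA()]: computes the kinship coefficient phi(i, j) by
#' the classic pairwise recursion with memoization and returns the additive
#' relationship 2*phi(i, j) (which on the diagonal equals 1 + F_i). Used as
#' a cross-check oracle for the tabular method.
#'
#' @param pedigree a [Pedigree-class]
#' @param i,j individual ids
#' @return the additive relationship (a single number)
#' @export
kinshipCoef <- function(pedigree, i, j) {
  stopifnot(is(pedigree, "Pedigree"))
  pos <- stats::setNames(seq_along(pedigree@id), pedigree@id)
  if (!i %in% pedigree@id) stop("unknown id: ", i)
  if (!j %in% pedigree@id) stop("unknown id: ", j)
  si <- stats::setNames(pedigree@sire, pedigree@id)
  di <- stats::setNames(pedigree@dam, pedigree@id)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    # order so the later-born (topologically) individual comes first
    if (pos[a] < pos[b]) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, b, sep = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      0.5 * (1 + phi(si[[a]], di[[a]]))
    } else {
      0.5 * (phi(si[[a]], b) + phi(di[[a]], b))
    }
    memo[[key]] <- val
    val
  }
  2 * phi(i, j)
}
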