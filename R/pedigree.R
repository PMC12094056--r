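#' Pedigree construction and validation
#'
#' Build a pedigree object from animal/sire/dam triples.  Unknown parents are
#' coded `0`, `NA` or `""` on input (the BLUPF90 convention for delimited
#' files uses `0`).  Animals are reordered so that every parent precedes its
#' offspring, and ids are remapped to dense integer indices; the original ids
#' are retained in `$id`.
#'
#' Parents that appear only in the sire or dam column are added as founder
#' rows (a message reports how many).  A cycle (an animal that is its own
#' ancestor) is an error naming one animal on the cycle, as is an animal with
#' `sire == dam`.
#'
#' @param animal,sire,dam vectors of ids (character or numeric).
#' @return An object of class `pedigree`: a list with `id` (original ids in
#'   topological order), `sire`/`dam` (integer indices into `id`, `NA` for
#'   unknown) and `n`.
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(animal) != length(sire) || length(animal) != length(dam))
    stop("animal, sire and dam must have equal length")
  if (anyDuplicated(animal))
    stop("duplicated animal id: ", animal[duplicated(animal)][1L])
  miss <- function(x) is.na(x) | x == "0" | x == ""
  sire[miss(sire)] <- NA_character_
  dam[miss(dam)] <- NA_character_
  bad <- !is.na(sire) & !is.na(dam) & sire == dam
  if (any(bad))
    stop("sire equals dam for animal ", animal[bad][1L])
  self <- (!is.na(sire) & sire == animal) | (!is.na(dam) & dam == animal)
  if (any(self))
    stop("pedigree cycle detected involving animal ", animal[self][1L])

  extra <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(extra)) {
    message(length(extra), " parent id(s) absent as animal rows; added as founders")
    animal <- c(animal, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
  }

  n <- length(animal)
  idx <- match(animal, animal)
  si <- match(sire, animal)
  di <- match(dam, animal)

  # Kahn topological sort over parent -> offspring edges
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order_out <- integer(n)
  queue <- which(indeg == 0L)
  k <- 0L
  while (length(queue)) {
    # preserve input order among ties for reproducibility
    v <- queue[1L]
    queue <- queue[-1L]
    k <- k + 1L
    order_out[k] <- v
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (k < n) {
    on_cycle <- setdiff(seq_len(n), order_out[seq_len(k)])
    stop("pedigree cycle detected involving animal ", animal[on_cycle[1L]])
  }
  pos <- integer(n)
  pos[order_out] <- seq_len(n)
  ped <- list(
    id = animal[order_out],
    sire = pos[si][order_out],
    dam = pos[di][order_out],
    n = n
  )
  class(ped) <- "pedigree"
  ped
}

#' Read a three-column pedigree file
#'
#' Reads `animal,sire,dam` (header optional, comma- or whitespace-delimited)
#' with `0` meaning unknown parent, and returns a validated, topologically
#' ordered [pedigree].
#'
#' @param path file path.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  dt <- data.table::fread(path, header = "auto", colClasses = "character")
  if (ncol(dt) < 3L) stop("pedigree file must have 3 columns: animal, sire, dam")
  pedigree(dt[[1L]], dt[[2L]], dt[[3L]])
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat("pedigree: ", x$n, " animals (", nf, " founders)\n", sep = "")
  invisible(x)
}

#' Numerator relationship matrix
#'
#' Dense additive relationship matrix A by the tabular method:
#' `A[j, i] = 0.5 * (A[j, s(i)] + A[j, d(i)])` for `j` preceding `i`
#' (unknown parents contribute 0) and `A[i, i] = 1 + 0.5 * A[s(i), d(i)]`.
#' Intended for pedigrees up to a few thousand animals; use
#' [build_A_inverse()] for the sparse inverse at scale.
#'
#' @param ped a [pedigree].
#' @return Dense numeric matrix with dimnames `ped$id`.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    if (i > 1L) {
      js <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[js, s]
      if (!is.na(d)) row <- row + A[js, d]
      row <- 0.5 * row
      A[js, i] <- row
      A[i, js] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficient F by the Meuwissen-Luo ancestor-tracing
#' recursion, identical to `diag(build_A(ped)) - 1` but without materializing
#' A.
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of F in `[0, 1)`.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  F <- numeric(n)
  Dv <- numeric(n)  # Mendelian-sampling variance, needs parents' F only
  L <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    Dv[i] <- 1 -
      (if (!is.na(s)) 0.25 * (1 + F[s]) else 0) -
      (if (!is.na(d)) 0.25 * (1 + F[d]) else 0)
    if (is.na(s) || is.na(d)) {
      F[i] <- 0  # unknown parents are unrelated founders
      next
    }
    # A_ii = sum over ancestors j of L_j^2 D_j with L_i = 1; trace the
    # ancestor set youngest-first so contributions are complete when popped
    L[s] <- 0.5
    L[d] <- L[d] + 0.5
    active <- sort(unique(c(s, d)), decreasing = TRUE)
    aii <- Dv[i]  # the animal's own term (L_i = 1)
    while (length(active)) {
      j <- active[1L]
      active <- active[-1L]
      aii <- aii + L[j]^2 * Dv[j]
      for (p in c(ped$sire[j], ped$dam[j])) {
        if (!is.na(p)) {
          if (L[p] == 0) active <- sort(c(active, p), decreasing = TRUE)
          L[p] <- L[p] + 0.5 * L[j]
        }
      }
      L[j] <- 0
    }
    F[i] <- aii - 1
  }
  names(F) <- ped$id
  F
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding.  For each animal the Mendelian-sampling
#' variance is `d = 1 - 0.25 (1 + F_sire) - 0.25 (1 + F_dam)` with a term
#' dropped when the parent is unknown; `1/d`, `-0.5/d` and `0.25/d` are added
#' to the (animal, sire, dam) block.
#'
#' @param ped a [pedigree].
#' @param f inbreeding coefficients as returned by [inbreeding()]; computed
#'   when missing.
#' @return A sparse symmetric `Matrix::dgCMatrix` with dimnames `ped$id`.
#' @export
build_A_inverse <- function(ped, f = inbreeding(ped)) {
  stopifnot(inherits(ped, "pedigree"), length(f) == ped$n)
  s <- ped$sire
  d <- ped$dam
  Fs <- ifelse(is.na(s), NA_real_, f[ifelse(is.na(s), 1L, s)])
  Fd <- ifelse(is.na(d), NA_real_, f[ifelse(is.na(d), 1L, d)])
  dv <- 1 -
    ifelse(is.na(s), 0, 0.25 * (1 + Fs)) -
    ifelse(is.na(d), 0, 0.25 * (1 + Fd))
  if (any(dv <= 0))
    stop("non-positive Mendelian-sampling variance for animal ",
         ped$id[which(dv <= 0)[1L]], " (invalid inbreeding input)")
  b <- 1 / dv
  ii <- seq_len(ped$n)

  ti <- ii; tj <- ii; tx <- b
  hs <- !is.na(s)
  hd <- !is.na(d)
  add <- function(i, j, x) {
    ti <<- c(ti, i, j)
    tj <<- c(tj, j, i)
    tx <<- c(tx, x, x)
  }
  if (any(hs)) {
    add(ii[hs], s[hs], -0.5 * b[hs])
    ti <- c(ti, s[hs]); tj <- c(tj, s[hs]); tx <- c(tx, 0.25 * b[hs])
  }
  if (any(hd)) {
    add(ii[hd], d[hd], -0.5 * b[hd])
    ti <- c(ti, d[hd]); tj <- c(tj, d[hd]); tx <- c(tx, 0.25 * b[hd])
  }
  both <- hs & hd
  if (any(both)) add(s[both], d[both], 0.25 * b[both])
  Ainv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                               dims = c(ped$n, ped$n),
                               dimnames = list(ped$id, ped$id))
  Matrix::drop0(Ainv)
}

#' Truncate a pedigree to a fixed ancestor depth
#'
#' Keeps each animal in `keep` together with its ancestors up to `depth`
#' generations; deeper ancestors become unknown founder parents.
#'
#' @param ped a [pedigree].
#' @param keep ids of the animals of interest (typically the phenotyped cows).
#' @param depth generations of ancestors to retain (default 5).
#' @return A new [pedigree] restricted to the retained animals.
#' @export
truncate_pedigree <- function(ped, keep, depth = 5L) {
  stopifnot(inherits(ped, "pedigree"), depth >= 0L)
  keep_idx <- match(as.character(keep), ped$id)
  if (anyNA(keep_idx))
    stop("keep contains ids not in the pedigree: ",
         paste(utils::head(setdiff(as.character(keep), ped$id), 5L), collapse = ", "))
  # level = fewest generations separating an animal from the keep set
  level <- rep.int(NA_integer_, ped$n)
  level[keep_idx] <- 0L
  frontier <- keep_idx
  g <- 0L
  while (length(frontier) && g < depth) {
    g <- g + 1L
    parents <- unique(stats::na.omit(c(ped$sire[frontier], ped$dam[frontier])))
    new <- parents[is.na(level[parents])]
    level[new] <- g
    frontier <- new
  }
  retained <- which(!is.na(level))
  in_set <- logical(ped$n)
  in_set[retained] <- TRUE
  parent_id <- function(p) {
    out <- rep.int("0", length(p))
    ok <- !is.na(p) & in_set[ifelse(is.na(p), 1L, p)]
    out[ok] <- ped$id[p[ok]]
    out
  }
  pedigree(ped$id[retained],
           parent_id(ped$sire[retained]),
           parent_id(ped$dam[retained]))
}

#' Export a sparse A-inverse as coordinate triplets
#'
#' Writes MatrixMarket coordinate format, readable by `Matrix::readMM` and
#' by scipy / BLUPF90-adjacent tooling.
#'
#' @param Ainv sparse matrix from [build_A_inverse()].
#' @param path output file.
#' @export
write_A_inverse <- function(Ainv, path) {
  Matrix::writeMM(methods::as(Ainv, "generalMatrix"), path)
  invisible(path)
}
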