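# Full-matrix recursive-kinship oracle, written independently of the
# package's tabular method: phi(i,j) by pairwise recursion with a shared
# memo table, returned as additive relationships 2*phi.
oracleA <- function(ped) {
  id <- ids(ped)
  n <- length(id)
  pos <- setNames(seq_len(n), id)
  s <- sires(ped)
  d <- dams(ped)
  memo <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    if (pos[[a]] < pos[[b]]) { t <- a; a <- b; b <- t }
    key <- paste(a, b)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) 0.5 * (1 + phi(s[[a]], d[[a]]))
           else 0.5 * (phi(s[[a]], b) + phi(d[[a]], b))
    memo[[key]] <- val
    val
  }
  M <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in seq_len(i))
    M[i, j] <- M[j, i] <- 2 * phi(id[i], id[j])
  M
}
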