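# Small dense-tensor helpers. All likelihood arrays in this package are tiny
# (hundreds of entries), so plain reshape-and-multiply is both adequate and
# transparent.

# tensor-times-vector: contract array `a` with vector `v` along dimension `d`
ttv <- function(a, v, d) {
  dims <- dim(a) %||% length(a)
  if (length(dims) == 1) {
    stopifnot(d == 1)
    return(sum(a * v))
  }
  perm <- c(setdiff(seq_along(dims), d), d)
  ap <- aperm(a, perm)
  m <- matrix(ap, ncol = dims[d])
  res <- as.numeric(m %*% v)
  newdim <- dims[perm][-length(perm)]
  if (length(newdim) <= 1) res else array(res, dim = newdim)
}

# contract array over ALL dims using one probability vector per dim -> scalar
ttv_all <- function(a, vs) {
  for (i in rev(seq_along(vs))) a <- ttv(a, vs[[i]], i)
  as.numeric(a)
}

# contract over all dims EXCEPT `keep` -> vector over dim `keep`
ttv_except <- function(a, vs, keep) {
  dims <- seq_along(dim(a) %||% 1L)
  for (d in rev(setdiff(dims, keep))) {
    a <- ttv(a, vs[[d]], d)
    # dims after d shift down by one; `keep` too if it was above d
    if (keep > d) keep <- keep - 1L
  }
  as.numeric(a)
}

# outer product of a list of vectors, as an array
outer_list <- function(vs) {
  out <- vs[[1]]
  if (length(vs) > 1) {
    for (i in 2:length(vs)) out <- outer(out, vs[[i]])
  }
  array(out, dim = vapply(vs, length, integer(1)))
}
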