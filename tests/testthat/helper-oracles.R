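# Independent oracles used by the unit tests. These deliberately avoid
# the package's own dynamic-programming code paths: alignment scores come
# from exhaustive enumeration of alignments, graph components from a
# hand-rolled DFS, and tree topologies from least-squares over all
# candidate topologies.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomAA <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Exhaustive global alignment score by recursion over all alignments.
# Gap of length g costs open + (g-1)*ext; state tracks whether the
# previous column was a gap in the same sequence (extension pricing).
bruteGlobalScore <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  rec <- function(i, j, prev) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    if (i <= na)
      best <- max(best,
                  -(if (prev == "X") ext else open) + rec(i + 1, j, "X"))
    if (j <= nb)
      best <- max(best,
                  -(if (prev == "Y") ext else open) + rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "M")
}

# Exhaustive local score: best global score over all substring pairs
# (empty alignment scores 0).
bruteLocalScore <- function(a, b, mat, open, ext) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0
  for (i1 in 1:na) for (i2 in i1:na) for (j1 in 1:nb) for (j2 in j1:nb) {
    s <- bruteGlobalScore(substr(a, i1, i2), substr(b, j1, j2),
                          mat, open, ext)
    if (s > best) best <- s
  }
  best
}

# Connected components by depth-first search over an edge list.
dfsComponents <- function(nodes, edgesA, edgesB) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(edgesA)) {
    adj[[edgesA[k]]] <- c(adj[[edgesA[k]]], edgesB[k])
    adj[[edgesB[k]]] <- c(adj[[edgesB[k]]], edgesA[k])
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (n in nodes) {
    if (!is.na(comp[n])) next
    cur <- cur + 1L
    stack <- n
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]])
    }
  }
  comp
}

# Best tree topology for a distance matrix by ordinary least squares over
# all unrooted topologies (via phangorn's topology enumeration and design
# matrices).
lsBestTopology <- function(d) {
  labs <- attr(as.dist(d), "Labels")
  trees <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  dv <- as.vector(as.dist(d))
  rss <- vapply(trees, function(tr) {
    X <- phangorn::designTree(tr)
    fit <- lm.fit(as.matrix(X), dv)
    sum(fit$residuals^2)
  }, numeric(1))
  trees[[which.min(rss)]]
}

# Naive end-trimming oracle: scan all (left, right) column windows.
bruteComparableSegment <- function(alignedA, alignedB, minLength) {
  ga <- strsplit(alignedA, "")[[1]]
  gb <- strsplit(alignedB, "")[[1]]
  L <- length(ga)
  bestVal <- -Inf; best <- NULL
  for (l in seq_len(L)) for (r in l:L) {
    win <- l:r
    nA <- sum(ga[win] != "-")
    nB <- sum(gb[win] != "-")
    if (nA < minLength || nB < minLength) next
    v <- sum(ga[win] != "-" & gb[win] != "-" & ga[win] == gb[win]) -
      sum(ga[win] == "-" | gb[win] == "-")
    if (v > bestVal) { bestVal <- v; best <- c(l, r) }
  }
  list(value = bestVal, columns = best)
}

# Small helper: named character vector out of an AAStringSet.
chr <- function(x) {
  nms <- names(x)
  out <- as.character(x)
  names(out) <- nms
  out
}
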