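## Fixture builders and independent oracles used across the suite.

random_alignment <- function(n_taxa, n_cols, gap_prob = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_taxa * n_cols, replace = TRUE),
              nrow = n_taxa)
  if (gap_prob > 0)
    m[matrix(runif(n_taxa * n_cols) < gap_prob, nrow = n_taxa)] <- "-"
  rownames(m) <- sprintf("t%02d", seq_len(n_taxa))
  raw_alignment(m)
}

## Related sequences: a common ancestor row with per-taxon mutations, so
## pairwise divergence stays far from Jukes-Cantor saturation.
related_alignment <- function(n_taxa, n_cols, div = 0.15, gap_prob = 0,
                              seed = 1) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  m <- t(vapply(seq_len(n_taxa), function(i) {
    v <- anc
    mut <- which(runif(n_cols) < div)
    v[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    if (gap_prob > 0) v[runif(n_cols) < gap_prob] <- "-"
    v
  }, character(n_cols)))
  rownames(m) <- sprintf("t%02d", seq_len(n_taxa))
  raw_alignment(m)
}

## A 100 bp toy genome with one forward CDS at 0-based [10, 40).
toy_genome <- function() {
  set.seed(42)
  res <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  annotated_genome("toy", res, list(
    list(name = "rbcL", kind = "CDS",
         intervals = matrix(c(10, 40), ncol = 2), strand = "+")))
}

random_inframe_pair <- function(n_codons, seed, gap_prob = 0.05) {
  set.seed(seed)
  sense <- rownames(.ng_site_oracle_table())
  c1 <- sample(sense, n_codons, replace = TRUE)
  c2 <- c1
  ## mutate some codons of c2 (keeping them sense)
  mut <- runif(n_codons) < 0.4
  c2[mut] <- sample(sense, sum(mut), replace = TRUE)
  gap <- runif(n_codons) < gap_prob
  c2[gap] <- "---"
  list(seq1 = paste(c1, collapse = ""), seq2 = paste(c2, collapse = ""))
}

## ---- independent Nei-Gojobori oracle (seqinr translation, explicit
## ---- enumeration; shares no code with the package implementation) ----

.ng_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

.ng_site_oracle_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    bases <- c("A", "C", "G", "T")
    all_codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                        collapse = "")
    sense <- all_codons[vapply(all_codons, .ng_translate, "") != "*"]
    S <- vapply(sense, function(cd) {
      nt <- strsplit(cd, "")[[1]]
      total <- 0
      for (pos in 1:3) {
        neigh <- vapply(setdiff(bases, nt[pos]), function(b) {
          x <- nt; x[pos] <- b; paste(x, collapse = "")
        }, "")
        aa <- vapply(neigh, .ng_translate, "")
        keep <- aa != "*"
        if (any(keep))
          total <- total + sum(aa[keep] == .ng_translate(cd)) / sum(keep)
      }
      total
    }, numeric(1))
    tab <<- data.frame(S = S, N = 3 - S, row.names = sense)
    tab
  }
})

.ng_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .ng_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

.ng_path_diffs_oracle <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0L) return(c(0, 0))
  walk <- function(order, allow_stop) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      if (!allow_stop && .ng_translate(paste(nxt, collapse = "")) == "*")
        return(NULL)
      if (.ng_translate(paste(cur, collapse = "")) ==
          .ng_translate(paste(nxt, collapse = ""))) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- Filter(Negate(is.null),
                  lapply(.ng_perms(pos), walk, allow_stop = FALSE))
  if (length(paths) == 0L) paths <- lapply(.ng_perms(pos), walk,
                                           allow_stop = TRUE)
  colMeans(do.call(rbind, paths))
}

## Full independent dN/dS oracle for an in-frame pair.
ng_dnds_oracle <- function(seq1, seq2) {
  split3 <- function(s) substring(toupper(s), seq(1, nchar(s), 3),
                                  seq(3, nchar(s), 3))
  c1 <- split3(seq1); c2 <- split3(seq2)
  tab <- .ng_site_oracle_table()
  ok <- c1 %in% rownames(tab) & c2 %in% rownames(tab)
  S <- 0; N <- 0; sd <- 0; nd <- 0
  for (i in which(ok)) {
    S <- S + (tab[c1[i], "S"] + tab[c2[i], "S"]) / 2
    N <- N + (tab[c1[i], "N"] + tab[c2[i], "N"]) / 2
    d <- .ng_path_diffs_oracle(c1[i], c2[i])
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  pS <- if (S > 0) sd / S else 0
  pN <- if (N > 0) nd / N else 0
  list(dN = -0.75 * log(1 - 4 * pN / 3), dS = -0.75 * log(1 - 4 * pS / 3))
}

## ---- brute-force conflict oracle ----

conflict_groups_oracle <- function(entries, qualifying_ids) {
  n <- length(qualifying_ids)
  if (n == 0L) return(list())
  conflict <- function(a, b) {
    length(intersect(a, b)) > 0 && !all(a %in% b) && !all(b %in% a)
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    adj[i, j] <- conflict(entries[[qualifying_ids[i]]],
                          entries[[qualifying_ids[j]]])
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L || !any(adj[i, ])) next
    cur <- cur + 1L
    frontier <- i
    while (length(frontier) > 0L) {
      comp[frontier] <- cur
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
      frontier <- setdiff(nxt, which(comp > 0L))
    }
  }
  lapply(seq_len(cur), function(g) sort(qualifying_ids[comp == g]))
}

## Random rooted tree over a random leaf subset; returns clade list.
random_clade_set <- function(n_leaves, n_clades, seed) {
  set.seed(seed)
  leaves <- sprintf("L%d", seq_len(n_leaves))
  out <- list()
  while (length(out) < n_clades) {
    k <- sample(2:(n_leaves - 1), 1)
    cl <- sort(sample(leaves, k))
    out[[paste(cl, collapse = "|")]] <- cl
  }
  unname(out)
}
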