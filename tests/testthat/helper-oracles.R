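# Independent oracles used across the suite. These deliberately take
# different algorithmic routes from the package implementation: recursive
# memoized kinship instead of the tabular loop, the Wigginton recurrence
# instead of log-factorials for the Hardy-Weinberg exact test, and plain
# all-pairs loops instead of interval trees for overlaps.

# additive relationship a(i, j) by memoized recursion on parent indices
oracle_relationship <- function(ped) {
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  memo <- new.env(hash = TRUE)
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      1 + 0.5 * a(si[i], di[i])
    } else {
      0.5 * (a(si[i], j) + a(di[i], j))
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- a(i, j)
  A
}

oracle_inbreeding <- function(ped) {
  diag(oracle_relationship(ped)) - 1
}

# HWE exact p-value by the probability recurrence
# P(h + 2) / P(h) = (nA - h)(nB - h) / ((h + 2)(h + 1))
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  hs <- seq.int(nA %% 2, min(nA, nB), by = 2)
  pr <- numeric(length(hs))
  pr[1] <- 1
  if (length(hs) > 1) {
    for (t in seq_len(length(hs) - 1)) {
      h <- hs[t]
      pr[t + 1] <- pr[t] * (nA - h) * (nB - h) / ((h + 2) * (h + 1))
    }
  }
  pr <- pr / sum(pr)
  pobs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-9)]))
}

# all-pairs closed-interval overlap
oracle_overlaps <- function(windows, intervals) {
  hits <- NULL
  for (i in seq_len(nrow(windows))) {
    for (j in seq_len(nrow(intervals))) {
      if (windows$chrom[i] == intervals$chrom[j] &&
          windows$start[i] <= intervals$end[j] &&
          intervals$start[j] <= windows$end[i]) {
        hits <- rbind(hits, data.frame(w = i, g = j))
      }
    }
  }
  hits
}

# a random valid pedigree: founders plus animals with parents drawn from
# earlier animals (possibly unknown)
random_pedigree <- function(n, n_founders = max(3L, n %/% 4L), seed = 1L) {
  set.seed(seed)
  id <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1L):n) {
    cand <- seq_len(i - 1L)
    s <- sample(cand, 1); d <- sample(setdiff(cand, s), 1)
    if (stats::runif(1) < 0.15) s <- 0L     # some unknown parents
    sire[i] <- if (s == 0L) "0" else id[s]
    dam[i] <- id[d]
  }
  trace_and_sort(data.frame(animal_id = id, sire_id = sire, dam_id = dam))
}

# small record table with explicit values for filter tests
toy_records <- function() {
  data.frame(
    cow_id = c("c1", "c1", "c1", "c2", "c2", "c3", "c3", "c3", "c3"),
    herd = "H1",
    calving_date = as.Date("2018-03-01"),
    birth_date = as.Date("2016-01-15"),
    dim = c(10L, 100L, 200L, 20L, 120L, 50L, 110L, 170L, 230L),
    my = 30, fp = 4, pp = 3.2, scc = 150,
    stringsAsFactors = FALSE)
}
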