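# Shared fixtures: all synthetic, built in code at test time.

# scaled-down cage experiment for fast end-to-end tests
small_sim <- function(seed = 11) {
  simulation_config(seed = seed, guts_per_treatment = 8L, n_blanks = 8L,
                    sequencing_depth_mean = 8000, blank_depth_mean = 1000)
}

# tiny labeled abundance matrix
tiny_table <- function(seed = 1, n = 6, p = 5) {
  set.seed(seed)
  matrix(stats::rlnorm(n * p), n, p,
         dimnames = list(paste0("s", seq_len(n)), paste0("a", seq_len(p))))
}

# star phylogeny with unit branches
star_tree <- function(tips) {
  ape::read.tree(text = paste0("(", paste0(tips, ":1", collapse = ","), ");"))
}

# a noiseless standard curve with perfect doubling chemistry
perfect_curve <- function(intercept = 38) {
  copies <- 10^(1:6)
  fit_standard_curve(data.frame(copies = copies,
                                cq = intercept - log2(copies)))
}

# enumerate label assignments independently of the package's own
# enumeration: recursive position-choice over combn
oracle_label_perms <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  lev <- sort(unique(labels))
  sizes <- table(labels)[lev]
  out <- list()
  assign_rec <- function(remaining_pos, li, acc) {
    if (li > length(lev)) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    k <- sizes[[li]]
    if (length(remaining_pos) == k) {
      acc[remaining_pos] <- lev[li]
      assign_rec(integer(0), li + 1, acc)
      return(invisible())
    }
    picks <- utils::combn(remaining_pos, k)
    for (j in seq_len(ncol(picks))) {
      a2 <- acc
      a2[picks[, j]] <- lev[li]
      assign_rec(setdiff(remaining_pos, picks[, j]), li + 1, a2)
    }
  }
  assign_rec(seq_len(n), 1, character(n))
  do.call(rbind, out)
}
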