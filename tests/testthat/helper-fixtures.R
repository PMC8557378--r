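# shared analytic fixtures

cone_diameter <- function(h, H = 25, dbh = 30) dbh * (H - h) / (H - 1.3)
paraboloid_diameter <- function(h, H = 25, dbh = 30)
  dbh * sqrt(pmax(H - h, 0) / (H - 1.3))

cone_tree <- function() tree_metrics(25, 30, 15, tree_id = "cone")

# eight slices on cm-grid heights, exactly on the analytic taper
cone_slices <- function(H = 25, dbh = 30) {
  h <- c(0.3, 2, 5, 8, 11, 14, 18, 22)
  data.frame(height_m = h, diameter_cm = cone_diameter(h, H, dbh))
}

paraboloid_slices <- function(H = 25, dbh = 30) {
  h <- c(0.3, 2, 5, 8, 11, 14, 18, 22)
  data.frame(height_m = h, diameter_cm = paraboloid_diameter(h, H, dbh))
}

# brute-force single-linkage clustering oracle: O(n^2) region growing
brute_single_linkage <- function(heights, threshold = 0.03) {
  n <- length(heights)
  cl <- seq_len(n)
  repeat {
    merged <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (cl[i] != cl[j] && abs(heights[i] - heights[j]) <= threshold + 1e-12) {
        cl[cl == cl[j]] <- cl[i]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  unname(sort(sapply(split(heights, cl), mean), decreasing = TRUE))
}

# brute-force one-to-one whorl pairing over all assignments (tiny n)
brute_pair_counts <- function(ref_areas, est_areas) {
  nr <- length(ref_areas); ne <- length(est_areas)
  k <- min(nr, ne)
  if (k == 0) return(c(np = 0, nc = ne, no = nr))
  best <- Inf
  ref_sets <- utils::combn(nr, k, simplify = FALSE)
  for (rs in ref_sets) {
    perms <- if (ne == 1) list(1L) else apply(utils::combn(ne, k), 2, identity, simplify = FALSE)
    for (es in perms) {
      for (p in all_perms(es)) {
        cost <- sum(abs(ref_areas[rs] - est_areas[p]))
        best <- min(best, cost)
      }
    }
  }
  c(np = k, nc = ne - k, no = nr - k)
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}
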