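# Brute-force entropy oracle: enumerates pixels and windows one by one and
# evaluates the Shannon sums directly via table() on string keys. Shares no
# code path with entropy_components().
brute_force_entropies <- function(q) {
  h <- nrow(q); w <- ncol(q)
  tab <- table(as.vector(q))
  p <- as.numeric(tab) / (h * w)
  h_marginal <- -sum(p * log(p))
  keys <- character(0)
  for (i in seq_len(h - 1)) {
    for (j in seq_len(w - 1)) {
      keys <- c(keys, paste(q[i, j], q[i, j + 1], q[i + 1, j], q[i + 1, j + 1]))
    }
  }
  tj <- table(keys)
  pj <- as.numeric(tj) / length(keys)
  h_joint <- -sum(pj * log(pj))
  list(h_marginal = h_marginal, h_joint = h_joint)
}

# random binary intensity matrix with dimensions in [2, 6]
random_small_intensity <- function() {
  h <- sample(2:6, 1); w <- sample(2:6, 1)
  matrix(sample(c(0, 0.9), h * w, replace = TRUE), h, w)
}

# iid uniform intensity matrix
iid_uniform_image <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(n * n), n, n)
}

# minimal call-record data frame builder
call_records <- function(site = "S1", night, species, len) {
  data.frame(site_id = site, night_index = night, species_label = species,
             sequence_length_s = len, stringsAsFactors = FALSE)
}

# a site row for the scene generator
site_row <- function(c_top, c_side, id = "S001", g = 50) {
  data.frame(site_id = id, green_space_type = "park", size_class = 1L,
             c_top = c_top, c_side = c_side, g = g, stringsAsFactors = FALSE)
}
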