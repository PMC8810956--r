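# Shared fixtures, built in code at test time.

# small noiseless phantom with one lesion at a known spot
quiet_phantom <- function(seed = 42L, noise_sd = 0, n_lesions = 1L,
                          n_vessels = 2L) {
  generate_case(phantom_params(seed = seed, liver_hu_noise_sd = noise_sd,
                               n_lesions = n_lesions, n_vessels = n_vessels),
                case_id = sprintf("fix_%d", seed))
}

# multichannel volume of a quiet phantom (cached per session)
fixture_mcv <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- compose_channels(quiet_phantom()$volume)
    cache
  }
})

# a deterministic patch with recognisable content
fixture_patch <- function() {
  mcv <- fixture_mcv()
  extract_positive_patches(mcv, quiet_phantom()$lesion_centers[1, ],
                           sampling_config(patches_per_lesion = 1,
                                           jitter_limit = 0, seed = 1),
                           case_id = "fix_42")[[1]]
}

# tiny separable patch sets for model tests: bright-centre blobs vs flat
# background, built directly as raw arrays
synthetic_patch <- function(label, seed, case_id = "synth") {
  withr::with_seed(seed, {
    base <- array(as.integer(round(runif(32 * 32 * 8 * 3, 20, 60))),
                  dim = c(32, 32, 8, 3))
    if (label == "positive") {
      base[13:20, 13:20, 3:6, ] <- base[13:20, 13:20, 3:6, ] + 150L
    }
    structure(list(data = array(as.raw(pmin(base, 255L)), dim = dim(base)),
                   center = c(16L, 16L, 4L), label = label,
                   case_id = case_id,
                   id = sprintf("%s_%s_%d", case_id, label, seed),
                   augmented = FALSE),
              class = "ltp_patch")
  })
}

synthetic_patch_set <- function(n_pos, n_neg, seed0 = 100L,
                                case_id = "synth") {
  pos <- lapply(seq_len(n_pos), function(i)
    synthetic_patch("positive", seed0 + i, case_id))
  neg <- lapply(seq_len(n_neg), function(i)
    synthetic_patch("negative", seed0 + 1000L + i, case_id))
  structure(c(pos, neg), class = "patch_set")
}

# brute-force pairwise AUC oracle (ties count half)
pair_count_auc <- function(probs, labels) {
  pos <- probs[labels]
  neg <- probs[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
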