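# Shared fixtures: the worked-example comparison and small DCE objects.

example_perf <- function() {
  truth <- table_truth()
  simulate_trial(truth, seed = 1)  # ses = 0 -> exact truth
}

# printed standardized scores of the worked example, intervention/comparator
example_std_rounded <- list(
  intervention = c(0.65, 0.81, 0.60, 0.45, 0.80, 0.80, 0.86, 0.20),
  comparator   = c(0.76, 0.58, 0.80, 0.89, 0.60, 0.60, 0.51, 0.40))

# small design for fast unit tests (full 10x18 reserved for acceptance);
# needs >= 16 distinct sets so all 16 coefficients are identifiable
small_design <- function(seed = 3)
  optimize_design(n_subdesigns = 2, n_sets = 9, seed = seed, n_sweeps = 2)

p1_truth_beta <- function(scale = 4)
  weights_to_partworths(example_weights("P1"), scale = scale)
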