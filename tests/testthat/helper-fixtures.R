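# Shared fixtures: canonical parameter sets and assay designs built in code.

# Reference two-state parameters: sensitive/resistant LD50s and slopes of the
# MCF-7 / MCF-7-ADR system, drug-free baseline viability 0.9.
ref_two_pop <- function(v_max = 0.9) {
  two_pop_params(c_sens = 22.4, m_sens = 0.06, c_res = 79.7, m_res = 0.028,
                 f_sens = 1, v_max = v_max)
}

ref_single <- function() single_params(c = 37.0, m = 0.055, v_max = 0.9)

# 8-week time course with sensitive fraction declining from 0.95 to 0.4.
ref_time_course <- function(replicates = 4) {
  make_time_course_design(seq(0.95, 0.4, length.out = 8), ref_two_pop(),
                          replicates = replicates)
}

# Five reference mixtures at resistant fractions 0, 0.25, 0.5, 0.75, 1.
ref_mixture_design <- function(replicates = 4) {
  make_mixture_design(c(0, 0.25, 0.5, 0.75, 1), ref_two_pop(),
                      replicates = replicates)
}

# Deterministic permutation for shuffle-invariance checks.
with_seed_order <- function(n, seed = 77) {
  drmix:::with_local_seed(seed, sample.int(n))
}

one_group_design <- function(params = ref_single(), replicates = 4,
                             dose_panel = dox_dose_panel) {
  assay_design(list(g1 = params), dose_panel = dose_panel,
               replicates = replicates)
}
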