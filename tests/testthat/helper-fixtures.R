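# Shared fixtures: tiny deterministic inputs built in code.

zero_life_table <- function(max_age = 100) {
  data.frame(age = 0:max_age, p_month = 0)
}

# toy cohort used in several hand-computed oracles
toy_params <- function(q_pre = 0.6, q_post = 0.9, p_wait = 0.1,
                       p_periop = 0.05, s_long = 1, age0 = 60,
                       life_table = zero_life_table()) {
  procedure_params("toy", age0 = age0, q_pre = q_pre, q_post = q_post,
                   p_wait_death = p_wait, p_periop_death = p_periop,
                   s_long = s_long, horizon_years = 5,
                   life_table = life_table)
}

# one elicitation cell as a data.frame
cell_scores <- function(vas, panel = "original", round = 2L,
                        procedure_id = "P01", state = "pre") {
  data.frame(panel = panel, round = round,
             expert_id = sprintf("E%02d", seq_along(vas)),
             procedure_id = procedure_id, state = state, vas = vas,
             stringsAsFactors = FALSE)
}

small_panel <- function(panel = "original", n_experts = 12, seed = 1, ...) {
  panel_config(panel, n_experts = n_experts, seed = seed, ...)
}

small_truths <- function(n_proc = 3, n_gbd = 1, seed = 42) {
  generate_procedure_truth(n_proc, n_gbd, seed = seed)
}
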