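# shared fixtures: the standard parameterisation with the two study values
# of theta, and the standard high/low initial states
p_theta2 <- cr_params(theta = 2, mu = 9)
p_theta025 <- cr_params(theta = 0.25, mu = 3.5)
p_lh <- cr_params(theta = 1, mu = 8)

s_high <- season_state(1, 0.2, 0.2)
s_low <- season_state(1, 0.01, 0.01)

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
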