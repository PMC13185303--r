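# 5-compound toy used across benchmark and prediction tests:
# approved = {A, B, C}; top-2 lists are A: [D, B], B: [D, A], C: [E, D],
# so exactly two of the three approved queries have an approved hit in
# their top 2, and D collects 3 consensus votes with average rank 4/3.
toy_pipeline <- function() {
  pipeline_from_rows(list(
    A = c(D = 0.10, B = 0.20, C = 0.30, E = 0.40),
    B = c(D = 0.10, A = 0.20, C = 0.30, E = 0.40),
    C = c(E = 0.10, D = 0.20, A = 0.30, B = 0.40),
    D = c(A = 0.10, B = 0.20, C = 0.30, E = 0.40),
    E = c(A = 0.10, B = 0.20, C = 0.30, D = 0.40)
  ))
}
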