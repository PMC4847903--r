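# Shared fixtures: published reference measurements used as test oracles.

cell_line_counts <- function() {
  list(
    lcl = list(target = panel_count(383, 770), reference = panel_count(398, 770)),
    h522 = list(target = panel_count(513, 770), reference = panel_count(310, 770)),
    skbr3 = list(target = panel_count(639, 770), reference = panel_count(206, 770))
  )
}

# eleven biopsy cases with published (r, x), DISH counts and per-cell estimates
biopsy_fixture <- function() example_biopsy_cases()
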