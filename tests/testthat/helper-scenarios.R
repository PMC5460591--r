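# classify each replayed step as merge / split / freeze by the cycle-count
# change of the breakpoint graph against the fixed target genome
step_kinds <- function(scenario) {
  cur <- scenario$start
  kinds <- character(0)
  c0 <- breakpoint_graph(genome_pair(cur, scenario$end))$c
  for (op in scenario$steps) {
    cur <- apply_wdcj(cur, op)
    c1 <- breakpoint_graph(genome_pair(cur, scenario$end))$c
    kinds <- c(kinds, if (c1 > c0) "split" else if (c1 < c0) "merge" else "freeze")
    c0 <- c1
  }
  kinds
}
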