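# Worked-example networks used throughout the suite.

fig1_rules <- "n0 *= not n3
n1 *= (not n0) or n3
n2 *= not n1
n3 *= (not n2) or (not n4)
n4 *= n0 or n1"

# feed-forward loops on top of a sustained source; LDOI of the source is
# empty while its asynchronous DOI is not
fig2a_rules <- "A *= A
B *= (not A) or C or D
C *= B
D *= not B"

# negative self-loop upstream of a self-sustaining node
fig2c_rules <- "A *= not A
B *= A or B or not C
C *= C"

fig1_model <- function() parse_rules(fig1_rules)
fig1_net <- function() build_expanded(fig1_model())

mutual_activation <- function() parse_rules("A *= B\nB *= A")

random_test_model <- function(n, kbar = 1.5, rule_type = "nested_canalizing") {
  generate_model(n, max(1L, as.integer(round(kbar * n))), rule_type)
}
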