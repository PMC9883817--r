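# Workplace stress conditions: the 15 most frequent stress-related
# mentions observed on a large company-review site. One phrase per line;
# lines starting with "#" are comments. Matching is case-insensitive on
# whole-word boundaries with longest-match overlap resolution, so e.g.
# "extreme stress" wins over the embedded "stress".
stress
high stress
pressure
burnout
understaffing
heavy workload
exhaustion
stress levels
overworked
tension
high workload
extreme stress
mental stress
overload
pressure to perform
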