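# Alternative scenario: 10% of the habitual consumption of pasta, bacon
# and rocket lettuce per person per day is replaced by the corresponding
# seaweed-derived product (made from the kelp Saccharina latissima).
name: alternative
rules:
  - targets: ["Grains>Pasta"]
    replacement: "Algae>Seaweed pasta"
    fraction: 0.10
  - targets: ["Meat>Bacon"]
    replacement: "Algae>Seaweed bacon"
    fraction: 0.10
  - targets: ["Vegetables>Lettuce>Rocket lettuce"]
    replacement: "Algae>Seaweed lettuce"
    fraction: 0.10
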