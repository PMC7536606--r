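# One finite-state transition graph per service category. S0 is the
# shared start state. Transition conditions are evaluated in declaration
# order; the first match wins; an unmatched input self-loops with a
# re-prompt. Condition language: intent, intent:NAME, slots_complete,
# accept, reject, no_match, else.
food_explanation:
  states:
    - id: S0
      action: greet
      transitions:
        - {when: "intent", to: S1}
    - id: S1
      action: elicit_slot
      transitions:
        - {when: "slots_complete", to: S2}
        - {when: "else", to: S1}
    - id: S2
      action: answer
      transitions:
        - {when: "intent", to: S1}
        - {when: "else", to: S3}
    - id: S3
      action: close
      terminal: true
meal_suggestion:
  states:
    - id: S0
      action: greet
      transitions:
        - {when: "intent", to: S1}
    - id: S1
      action: elicit_slot
      transitions:
        - {when: "slots_complete", to: S2}
        - {when: "else", to: S1}
    - id: S2
      action: offer
      transitions:
        - {when: "reject", to: S2}
        - {when: "accept", to: S4}
        - {when: "intent", to: S1}
        - {when: "else", to: S4}
    - id: S4
      action: close
      terminal: true
proper_diet_tips:
  states:
    - id: S0
      action: greet
      transitions:
        - {when: "intent", to: S1}
    - id: S1
      action: elicit_slot
      transitions:
        - {when: "slots_complete", to: S2}
        - {when: "else", to: S1}
    - id: S2
      action: tip
      transitions:
        - {when: "intent", to: S1}
        - {when: "else", to: S3}
    - id: S3
      action: close
      terminal: true
eating_challenge:
  states:
    - id: S0
      action: greet
      transitions:
        - {when: "intent", to: S1}
    - id: S1
      action: elicit_slot
      transitions:
        - {when: "slots_complete", to: S2}
        - {when: "else", to: S1}
    - id: S2
      action: tip
      transitions:
        - {when: "intent", to: S1}
        - {when: "else", to: S3}
    - id: S3
      action: close
      terminal: true
history_recall:
  states:
    - id: S0
      action: greet
      transitions:
        - {when: "intent", to: S1}
    - id: S1
      action: elicit_slot
      transitions:
        - {when: "slots_complete", to: S2}
        - {when: "else", to: S1}
    - id: S2
      action: history
      transitions:
        - {when: "intent", to: S1}
        - {when: "else", to: S3}
    - id: S3
      action: close
      terminal: true
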