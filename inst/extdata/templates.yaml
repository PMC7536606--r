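# Response templates per action and caregiver education tier.
# basic: short sentences, no technical nutrient terms, no percentages.
# standard: plain language with key numbers.
# advanced: full numeric rationale (kcal and percent-of-energy figures).
greet:
  basic: "Hello! I can help with meals and eating for your loved one. What would you like to know?"
  standard: "Hello! I can help you manage your loved one's diet: food questions, meal ideas, and tips. How can I help?"
  advanced: "Hello! I can answer food and nutrition questions, recommend guideline-compliant meals, and share caregiving tips. How can I help?"
elicit_slot:
  basic: "{prompt}"
  standard: "{prompt}"
  advanced: "{prompt}"
reprompt:
  basic: "Sorry, I did not catch that. {prompt}"
  standard: "Sorry, I did not catch that. {prompt}"
  advanced: "Sorry, I did not quite get that. {prompt}"
clarify:
  basic: "Sorry, I did not understand. Can you say it another way?"
  standard: "Sorry, I did not understand that. Could you rephrase your request?"
  advanced: "Sorry, I could not match that to a known request. Could you rephrase it?"
apologize:
  basic: "Sorry, I could not finish that request. Let us try something else."
  standard: "I am sorry, I could not collect what I needed for that request. Let us try something else."
  advanced: "I am sorry, I could not collect the required details for that request, so I am setting it aside. Let us try something else."
suitability_verdict:
  basic: "{food} is {verdict_phrase} as a {meal} for him. {reason_simple}"
  standard: "{food} is {verdict_phrase} as a {meal}. {reason}"
  advanced: "{food} is {verdict_phrase} as a {meal}. {reason} Per 100 g it has {energy_kcal} kcal and {sugar_g} g sugar ({sugar_pct}% of energy from sugar)."
explain_food:
  basic: "{food} gives {energy_kcal} calories in a 100 gram portion. {reason_simple}"
  standard: "Per 100 g, {food} provides {energy_kcal} kcal, {protein_g} g protein, {carb_g} g carbohydrate and {fat_g} g fat. {reason}"
  advanced: "Per 100 g, {food} provides {energy_kcal} kcal: {protein_g} g protein, {carb_g} g carbohydrate ({sugar_g} g sugar), {fat_g} g fat, {fiber_g} g fiber, {sodium_mg} mg sodium. {reason}"
offer_snack:
  basic: "How about {food}? It is a healthy choice for him. {reason_simple}"
  standard: "I suggest {food} as a snack. {reason}"
  advanced: "I suggest {food} as a snack. {reason} Per 100 g it provides {energy_kcal} kcal with {sugar_g} g sugar."
offer_recipe:
  basic: "How about {recipe}? It takes {prep_time} minutes and fits his needs. Would you like it?"
  standard: "I recommend {recipe}: about {energy_kcal} kcal per serving, ready in {prep_time} minutes. {reason} Would you like it?"
  advanced: "I recommend {recipe}: {energy_kcal} kcal per serving with {protein_pct}% of energy from protein and {sugar_pct}% from sugar, ready in {prep_time} minutes. {reason} Would you like it?"
none_available:
  basic: "I am sorry, I could not find a good match. {reason_simple}"
  standard: "I could not find a suitable option: {reason}"
  advanced: "No candidate satisfied every constraint. Binding constraint: {reason}"
tip:
  basic: "{tip}"
  standard: "{tip}"
  advanced: "{tip}"
history:
  basic: "{summary}"
  standard: "{summary} Total energy: {total_kcal} calories over {n} meals."
  advanced: "{summary} Total energy intake: {total_kcal} kcal across {n} recorded meals."
missing_data:
  basic: "{prompt}"
  standard: "{prompt}"
  advanced: "{prompt}"
close:
  basic: "You are welcome. Take care!"
  standard: "Happy to help. Take care of yourself too!"
  advanced: "Happy to help. Reach out any time for meal ideas or caregiving tips. Take care!"
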