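# Default intent registry: five service categories.
# Slot types: food_concept, meal_type, count, minutes, window.
# `prefill` names a profile field used to fill the slot without asking.
intents:
  - name: FoodSuitability
    category: food_explanation
    slots:
      - {name: food, type: food_concept, required: true,
         prompt: "Which food are you asking about?"}
      - {name: meal, type: meal_type, required: true,
         prompt: "For which meal, or as a snack?"}
    utterances:
      - "is {food} good as a {meal} for my dad"
      - "is {food} good as a {meal}"
      - "is {food} ok for a {meal}"
      - "can he have {food} for {meal}"
      - "is {food} healthy as a {meal} for him"
  - name: ExplainFood
    category: food_explanation
    slots:
      - {name: food, type: food_concept, required: true,
         prompt: "Which food would you like to know about?"}
    utterances:
      - "tell me about {food}"
      - "what nutrients are in {food}"
      - "explain {food} nutrition"
      - "what is in {food}"
  - name: SuggestSnack
    category: meal_suggestion
    slots: []
    utterances:
      - "can you suggest a good snack"
      - "what is a healthy snack for him"
      - "suggest a snack"
      - "any good snack ideas"
  - name: RecommendRecipe
    category: meal_suggestion
    slots:
      - {name: meal, type: meal_type, required: true,
         prompt: "Which meal is this for?"}
      - {name: servings, type: count, required: true,
         prompt: "How many servings do you need?"}
      - {name: max_time, type: minutes, required: true,
         prompt: "How much cooking time do you have?",
         prefill: caregiver.time_limit}
    utterances:
      - "recommend a recipe for {meal}"
      - "what should i cook for {meal}"
      - "suggest a {meal} recipe"
      - "i need a recipe for {meal} tonight"
      - "can you recommend something for {meal}"
  - name: GetDietTip
    category: proper_diet_tips
    slots: []
    utterances:
      - "give me a tip on proper diet"
      - "any diet tips for him"
      - "how should he be eating"
      - "share a healthy eating tip"
  - name: EatingChallengeTip
    category: eating_challenge
    slots: []
    utterances:
      - "he refuses to eat what can i do"
      - "help with eating problems"
      - "tips for handling eating challenges"
      - "he will not finish his meals"
  - name: RecallHistory
    category: history_recall
    slots:
      - {name: window, type: window, required: true,
         prompt: "Would you like the daily or the weekly history?"}
    utterances:
      - "what did he eat {window}"
      - "recall his {window} diet history"
      - "show his {window} meals"
      - "review the {window} diet"
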